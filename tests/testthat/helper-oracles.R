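# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive route (loops, literal scans, closed forms) sharing no
# code with the functions it checks.

# Connected-component areas by iterative flood fill over the pixel grid.
flood_fill_areas <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    nb <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  } else {
    nb <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  areas <- integer(0)
  stack_r <- integer(h * w)
  stack_c <- integer(h * w)
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (mask[r0, c0] && !seen[r0, c0]) {
      top <- 1L
      stack_r[1] <- r0; stack_c[1] <- c0
      seen[r0, c0] <- TRUE
      area <- 0L
      while (top > 0L) {
        pr <- stack_r[top]; pc <- stack_c[top]
        top <- top - 1L
        area <- area + 1L
        for (k in seq_len(nrow(nb))) {
          rr <- pr + nb[k, 1]; cc <- pc + nb[k, 2]
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            top <- top + 1L
            stack_r[top] <- rr; stack_c[top] <- cc
          }
        }
      }
      areas <- c(areas, area)
    }
  }
  areas
}

flood_fill_count <- function(mask, min_area, connectivity = 8) {
  sum(flood_fill_areas(mask, connectivity) > min_area)
}

# Closed-form pooled-variance two-sample t (KO minus WT), two-sided p.
pooled_t_oracle <- function(wt, ko) {
  n1 <- length(wt); n2 <- length(ko)
  sp2 <- ((n1 - 1) * stats::var(wt) + (n2 - 1) * stats::var(ko)) / (n1 + n2 - 2)
  t <- (mean(ko) - mean(wt)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2), df = n1 + n2 - 2)
}

# Explicit sums-of-squares decomposition for a balanced 2x2 factorial.
anova_ss_oracle <- function(tab, response) {
  y <- tab[[response]]
  s <- as.character(tab$sex)
  g <- as.character(tab$genotype)
  stopifnot(length(unique(as.vector(table(s, g)))) == 1)  # balanced only
  gm <- mean(y)
  ms <- tapply(y, s, mean); mg <- tapply(y, g, mean)
  key <- paste(s, g)
  mc <- tapply(y, key, mean)
  ss_s <- sum(table(s) * (ms - gm)^2)
  ss_g <- sum(table(g) * (mg - gm)^2)
  ss_res <- sum((y - mc[key])^2)
  ss_tot <- sum((y - gm)^2)
  ss_int <- ss_tot - ss_s - ss_g - ss_res
  df_res <- length(y) - 4L
  ms_res <- ss_res / df_res
  F <- c(sex = ss_s, genotype = ss_g, `sex:genotype` = ss_int) / ms_res
  list(F = F, p = stats::pf(F, 1, df_res, lower.tail = FALSE),
       ss = c(sex = ss_s, genotype = ss_g, interaction = ss_int,
              residual = ss_res, total = ss_tot),
       df_res = df_res)
}

# Literal Benjamini-Hochberg step-up scan: returns the logical rejection set.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  istar <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) istar <- i
  reject <- logical(m)
  if (istar > 0) reject[ord[seq_len(istar)]] <- TRUE
  reject
}

# Structure volumes by a naive triple loop over voxels.
naive_volume_oracle <- function(atlas, jac) {
  dims <- dim(atlas$labels)
  sums <- stats::setNames(numeric(length(atlas$name_map)),
                          names(atlas$name_map))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      lab <- atlas$labels[i, j, k]
      if (lab > 0) {
        nm <- names(atlas$name_map)[match(lab, atlas$name_map)]
        sums[nm] <- sums[nm] + jac$values[i, j, k]
      }
    }
  sums * atlas$voxel_size^3
}

# Random test masks: sparse blob fields and dense noise fields.
random_blob_mask <- function(h, w, seed, fraction = 0.08) {
  sim <- simulate_ihc_image(ihc_sim_params(
    noise_sd = 0, signal_fraction = fraction, object_area_px = c(40, 400),
    image_shape = c(h, w), seed = seed))
  sim$mask
}

random_noise_mask <- function(h, w, seed, p = 0.25) {
  morphoquant:::with_seed(seed, matrix(stats::runif(h * w) < p, h, w))
}

# Small random balanced 2x2 table.
random_factorial_table <- function(n_per_cell, seed, effects = c(0, 0, 0)) {
  morphoquant:::with_seed(seed, {
    d <- cohort_design(n_per_cell)
    d$y <- stats::rnorm(nrow(d)) +
      effects[1] * (d$sex == "F") +
      effects[2] * (d$genotype == "KO") +
      effects[3] * (d$sex == "F" & d$genotype == "KO")
    d
  })
}
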