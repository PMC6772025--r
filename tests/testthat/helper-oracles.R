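# Independent oracles used below -------------------------------------------

# brute-force Spearman: explicit average ranks + product-moment formula +
# t CDF, written without cor()/rank() shortcuts shared with the implementation
brute_spearman <- function(x, y) {
  avrank <- function(v) {
    s <- sort(unique(v))
    pos <- lapply(s, function(u) which(v == u))
    r <- numeric(length(v))
    k <- 0
    for (p in pos) { r[p] <- k + (length(p) + 1) / 2; k <- k + length(p) }
    r
  }
  rx <- avrank(x); ry <- avrank(y)
  n <- length(x)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# brute-force step-up adjustment by direct enumeration
brute_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n * p[o] / seq_len(n)
  for (i in seq.int(n - 1, 1)) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# hand-computed split-plot decomposition
brute_splitplot <- function(df) {
  N <- nlevels(df$subject); r <- nlevels(df$region); g <- nlevels(df$group)
  gm <- mean(df$value)
  subj_mean <- tapply(df$value, df$subject, mean)
  grp_of <- tapply(as.character(df$group), df$subject, unique)
  grp_mean <- tapply(df$value, df$group, mean)
  reg_mean <- tapply(df$value, df$region, mean)
  cell_mean <- tapply(df$value, list(df$group, df$region), mean)
  n_per_g <- table(factor(unlist(grp_of)))

  ss_group <- r * sum(n_per_g * (grp_mean - gm)^2)
  ss_subj <- r * sum((subj_mean - grp_mean[grp_of])^2)
  ss_region <- N * sum((reg_mean - gm)^2)
  ss_int <- sum(vapply(levels(df$group), function(gg)
    n_per_g[gg] * sum((cell_mean[gg, ] - grp_mean[gg] - reg_mean + gm)^2),
    numeric(1)))
  fit_cell <- cell_mean[cbind(as.character(df$group), as.character(df$region))]
  resid <- df$value - subj_mean[df$subject] - fit_cell +
    grp_mean[df$group]
  ss_res <- sum(resid^2)
  list(F_group = (ss_group / (g - 1)) / (ss_subj / (N - g)),
       F_region = (ss_region / (r - 1)) / (ss_res / ((r - 1) * (N - g))),
       F_int = (ss_int / ((g - 1) * (r - 1))) / (ss_res / ((r - 1) * (N - g))))
}

rm_design <- function(n_case = 9, n_ctrl = 6, regions = 3, seed = 1) {
  build <- function() {
    d <- expand.grid(subject = sprintf("s%02d", seq_len(n_case + n_ctrl)),
                     region = paste0("R", seq_len(regions)),
                     stringsAsFactors = TRUE)
    d$group <- factor(ifelse(as.integer(d$subject) <= n_case, "case", "control"))
    d$value <- rnorm(nrow(d))
    d
  }
  if (is.null(seed)) build() else with_seed_test(seed, build())
}

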