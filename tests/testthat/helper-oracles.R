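# Independent brute-force oracles, kept deliberately naive so they
# share no code path with the implementation they check.

# pixel-by-pixel loop over the image, no vectorisation
lso_oracle <- function(pixels, t_low, t_high) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      v <- pixels[i, j]
      if (v > t_low) n <- n + 1L
      if (v > t_high) s <- s + v
    }
  }
  list(sum_high = s, n_low = n,
       ratio = if (n > 0L) s / n else NA_real_)
}

# textbook Pearson formula written out longhand
pearson_oracle <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# a small synthetic Vina PDBQT result fixture
vina_pdbqt_fixture <- function(affinities) {
  header <- c("MODEL 1", "REMARK  Name = ligand")
  unlist(lapply(seq_along(affinities), function(i) {
    c(sprintf("MODEL %d", i),
      sprintf("REMARK VINA RESULT:    %6.1f      0.000      0.000",
              affinities[i]),
      "ATOM      1  C   LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 C",
      "ENDMDL")
  }))
}

vina_log_fixture <- function(affinities) {
  c("mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%4d %12.1f %10.3f %10.3f", seq_along(affinities),
            affinities, 0, 0))
}

# deterministic group fixtures for the normality gate:
# 'normal_scores' passes Shapiro-Wilk by construction (exact normal
# quantiles), 'heavy_tail' fails it (single gross outlier).
normal_scores <- function(n, mean = 0, sd = 1) {
  mean + sd * qnorm((seq_len(n) - 0.5) / n)
}
heavy_tail_fixture <- c(0.95, 0.98, 1.00, 1.01, 1.02, 1.03, 1.05, 52.0)
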