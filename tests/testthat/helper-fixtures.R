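# Small in-code fixtures shared across tests.

# A short strictly increasing grid.
tiny_grid <- function(n = 12, lo = 600, hi = 710) seq(lo, hi, length.out = n)

# Random spectrum set on a given grid.
random_set <- function(n_spec = 3, grid = tiny_grid(), seed = 1,
                       labels = NULL) {
  set.seed(seed)
  meta <- data.frame(spectrum_id = paste0("S", seq_len(n_spec)),
                     stringsAsFactors = FALSE)
  if (!is.null(labels)) meta$label <- labels
  spectrum_set(grid, matrix(rnorm(n_spec * length(grid)), n_spec), meta)
}

# Small, fast cohort configuration (noise-free and fully concordant unless
# overridden) for pipeline tests.
tiny_cohort <- function(n_intact = 24, n_damaged = 8, ...) {
  args <- list(n_intact = n_intact, n_damaged = n_damaged, n_subjects = 4,
               wavenumber = seq(600, 1800, by = 4), seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

# Direct least-squares oracle used against EMSC and PLS.
ols_fit <- function(X, y) qr.coef(qr(cbind(1, X)), y)

# Brute-force AUC: concordant pairs + half ties over all pos/neg pairs.
pair_count_auc <- function(scores, truth, positive = "damaged") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
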