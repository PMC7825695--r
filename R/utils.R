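#' @keywords internal
"_PACKAGE"

# Machine epsilon used in entropy-style logs, matching the convention of
# standard radiomics platforms.
.EPS <- 2.2e-16

#' Derive a reproducible substream seed
#'
#' Expands one master seed into independent per-unit seeds (per patient, per
#' resampling round, ...) so that unit `i` receives the same random stream
#' regardless of how many other units are generated.
#'
#' @param master integer master seed.
#' @param i integer unit index (>= 0).
#' @param tag character stream label, so different uses of the same index do
#'   not collide.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, i, tag = "") {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(i))
  h <- if (nzchar(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) else 0
  # 2^31 - 1 is prime; simple LCG-style mixing keeps everything in range
  s <- (abs(master) %% 2147483647) * 1
  s <- (s * 48271 + i * 16807 + h * 69621) %% 2147483647
  as.integer(s)
}

# stratified sample of size m from binary labels; guarantees both classes
# whenever m >= 2 and both classes exist
.stratified_sample <- function(labels, m) {
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  m1 <- max(1L, min(length(idx1), round(m * length(idx1) / length(labels))))
  m0 <- m - m1
  if (m0 > length(idx0)) {
    m0 <- length(idx0)
    m1 <- m - m0
  }
  if (m0 < 1L) {
    m0 <- 1L
    m1 <- m - 1L
  }
  sort(c(
    sample(idx1, m1),
    sample(idx0, m0)
  ))
}

# stratified k-fold assignment; returns integer vector of fold ids
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.assert_binary <- function(x, name = "labels") {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("'%s' must contain only 0/1 values", name), call. = FALSE)
  }
  invisible(TRUE)
}
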