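# Verification against published reference statistics.
#
# The package ships the printed 2x2 contingency tables (gene / interaction
# conservation of mitotic-hit vs other entities at the 70% cutoff) and the
# printed fragmentation Z-test triples of the reference mitosis RNAi screen
# conservation study, and recomputes the corresponding statistics with the
# package's own routines.

#' Load the shipped reference statistics
#'
#' @param path Path to a reference-tables JSON; defaults to the file shipped
#'   with the package.
#' @return List with elements `fisher` (data frame: `id`, counts `a`, `b`,
#'   `c`, `d`, `printed`, `digits`) and `ztest` (data frame: `id`,
#'   `observed`, `null_mean`, `null_sd`, `printed`, `digits`).
#' @export
reference_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_tables.json",
                        package = "mitonet")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fisher <- raw$fisher
  cn <- do.call(rbind, fisher$counts)
  fisher <- data.frame(id = fisher$id, a = cn[, 1], b = cn[, 2],
                       c = cn[, 3], d = cn[, 4], printed = fisher$printed,
                       digits = fisher$digits)
  ztest <- data.frame(id = raw$ztest$id, observed = raw$ztest$observed,
                      null_mean = raw$ztest$null_mean,
                      null_sd = raw$ztest$null_sd,
                      printed = raw$ztest$printed, digits = raw$ztest$digits)
  list(fisher = fisher, ztest = ztest)
}

#' Recompute and verify the reference statistics
#'
#' Recomputes each one-sided Fisher exact p-value from its printed
#' contingency table and each one-sided Z-test p-value from its printed
#' observed/mean/sd triple, and compares to the printed value at printed
#' precision (computed value rounded to the printed number of significant
#' digits).
#'
#' @param path Optional path to a reference-tables JSON (see
#'   [reference_tables()]).
#' @return Data frame with columns `id`, `kind`, `printed`, `computed`,
#'   `match`.
#' @export
#' @examples
#' all(verify_reference_stats()$match)
verify_reference_stats <- function(path = NULL) {
  ref <- reference_tables(path)
  f <- ref$fisher
  f_comp <- vapply(seq_len(nrow(f)), function(i) {
    fisher_exact_one_sided(f$a[i], f$b[i], f$c[i], f$d[i])$p_value
  }, numeric(1))
  z <- ref$ztest
  z_comp <- vapply(seq_len(nrow(z)), function(i) {
    z_test_decrease(z$observed[i], z$null_mean[i], z$null_sd[i])$p_value
  }, numeric(1))
  # equality at printed precision, robust to floating-point representation
  match_printed <- function(computed, printed, digits) {
    abs(signif(computed, digits) - printed) <= abs(printed) * 1e-8
  }
  out <- rbind(
    data.frame(id = f$id, kind = "fisher", printed = f$printed,
               computed = f_comp,
               match = match_printed(f_comp, f$printed, f$digits)),
    data.frame(id = z$id, kind = "ztest", printed = z$printed,
               computed = z_comp,
               match = match_printed(z_comp, z$printed, z$digits)))
  rownames(out) <- NULL
  out
}
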