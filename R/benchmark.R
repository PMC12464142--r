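#' Method-by-size binding energy table
#'
#' A complete matrix of binding energies (kcal/mol) for a set of
#' electronic-structure methods over a set of cluster sizes, with one
#' designated reference method (typically the coupled-cluster/CBS level)
#' against which the others are benchmarked.
#'
#' @param values numeric matrix, methods in columns, sizes in rows.
#' @param sizes integer cluster sizes, one per row.
#' @param methods method names, one per column.
#' @param reference name of the reference method (must be in `methods`).
#' @return object of class `"energy_table"`.
#' @export
energy_table <- function(values, sizes, methods, reference) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sizes), ncol(values) == length(methods))
  if (!reference %in% methods)
    stop("reference method '", reference, "' not among the table's methods")
  if (anyNA(values)) stop("binding-energy table has missing cells")
  dimnames(values) <- list(sizes, methods)
  obj <- list(values = values, sizes = as.integer(sizes),
              methods = methods, reference = reference)
  class(obj) <- "energy_table"
  obj
}

#' Read a binding-energy table from delimited text
#'
#' Expected layout: a header line `n,<method1>,<method2>,...` followed by
#' one row per cluster size, all cells numeric.
#'
#' @param path path to a comma-delimited file.
#' @param reference name of the reference method column.
#' @return an [energy_table()].
#' @export
read_energy_table <- function(path, reference) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (names(raw)[1] != "n")
    stop("first column must be the cluster size 'n'")
  methods <- names(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyNA(vals) || !is.numeric(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("non-numeric or missing cell at (method ", methods[bad[1, 2]],
         ", n = ", raw$n[bad[1, 1]], ")")
  }
  energy_table(vals, raw$n, methods, reference)
}

#' Published DFT benchmark table for hydrated imidazole
#'
#' Binding energies (kcal/mol) of the lowest-energy IMZ(H2O)_n clusters,
#' n = 1-8, for the five best-performing dispersion-corrected DFT
#' functionals together with the DLPNO-CCSD(T1)/CBS reference values.
#'
#' @return an [energy_table()] with reference `"CCSD(T)/CBS"`.
#' @export
imidazole_benchmark_table <- function() {
  path <- system.file("extdata", "dft_binding_energies.csv",
                      package = "microhydrate", mustWork = TRUE)
  read_energy_table(path, reference = "CCSD(T)/CBS")
}

#' Signed deviations from the reference method
#'
#' @param t an [energy_table()].
#' @return matrix (sizes x methods) of value minus reference, kcal/mol;
#'   the reference column is identically zero.
#' @export
deviations <- function(t) {
  stopifnot(inherits(t, "energy_table"))
  sweep(t$values, 1, t$values[, t$reference])
}

#' Deviation statistics of one method
#'
#' MAD is the mean absolute deviation, MAX the maximum absolute deviation,
#' and STD the population (divide-by-K) standard deviation of the signed
#' deviations about their mean. The population form is used because it
#' reproduces the conventional printed statistics for this benchmark; the
#' sample (K-1) variant does not.
#'
#' @param d numeric vector of signed deviations.
#' @return named numeric vector `c(MAD, MAX, STD)`.
#' @export
summary_stats <- function(d) {
  if (!length(d)) stop("empty deviation vector")
  c(MAD = mean(abs(d)),
    MAX = max(abs(d)),
    STD = sqrt(mean((d - mean(d))^2)))
}

# round half away from zero, matching how benchmark tables are printed
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Benchmark summary over all methods of a table
#'
#' @param t an [energy_table()].
#' @return object of class `"benchmark_summary"`: data.frame with columns
#'   `method`, `MAD`, `MAX`, `STD` (kcal/mol, full precision) ordered by
#'   the ranking of [rank_functionals()], with the table's reference in
#'   attribute `"reference"`.
#' @export
benchmark_summary <- function(t) {
  devs <- deviations(t)
  stats <- t(apply(devs, 2, summary_stats))
  out <- data.frame(method = rownames(stats), stats, row.names = NULL)
  ranked <- rank_functionals(out, reference = t$reference)
  out <- out[match(c(ranked, t$reference), out$method), ]
  row.names(out) <- NULL
  attr(out, "reference") <- t$reference
  class(out) <- c("benchmark_summary", "data.frame")
  out
}

#' Rank methods by accuracy
#'
#' Ascending mean absolute deviation, ties broken by STD, then by name.
#' The reference method is excluded from the ranking.
#'
#' @param s a [benchmark_summary()] or plain data.frame with columns
#'   `method`, `MAD`, `STD`.
#' @param reference reference method name to exclude (defaults to the
#'   summary's own reference attribute).
#' @return character vector of method names, most accurate first.
#' @export
rank_functionals <- function(s, reference = attr(s, "reference")) {
  d <- as.data.frame(s)
  if (!is.null(reference)) d <- d[d$method != reference, ]
  d$method[order(d$MAD, d$STD, d$method)]
}

#' @export
print.benchmark_summary <- function(x, digits = 1, ...) {
  cat("DFT benchmark vs", attr(x, "reference"), "(kcal/mol)\n")
  shown <- as.data.frame(x)
  for (col in c("MAD", "MAX", "STD"))
    shown[[col]] <- sprintf(paste0("%.", digits, "f"),
                            round_half_up(shown[[col]], digits))
  print(shown, row.names = FALSE)
  invisible(x)
}
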