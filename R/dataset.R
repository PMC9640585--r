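#' Construct a solubility dataset
#'
#' A solubility dataset is an ordered collection of (pressure, temperature,
#' mole-fraction solubility) observations for a solid solute equilibrated
#' with supercritical CO2. It is stored as a `data.frame` with columns
#' `pressure_bar`, `temperature_K` and `solubility_molefrac`, and carries a
#' `name` attribute.
#'
#' Units are fixed: pressure in bar, temperature in kelvin, solubility as a
#' mole fraction in (0, 1). Record identity is the (pressure, temperature)
#' pair; duplicates are rejected.
#'
#' @param pressure numeric vector of pressures in bar (positive).
#' @param temperature numeric vector of temperatures in kelvin (positive).
#' @param solubility numeric vector of mole fractions, each in (0, 1).
#' @param name label for the dataset.
#' @return An object of class `solubility_dataset`.
#' @examples
#' ds <- solubility_dataset(200, 318, 1.55e-4, name = "one point")
#' nrow(ds)
#' @export
solubility_dataset <- function(pressure, temperature, solubility,
                               name = "solubility data") {
  if (length(pressure) == 0L) stop("no records", call. = FALSE)
  stopifnot(length(pressure) == length(temperature),
            length(pressure) == length(solubility))
  ds <- data.frame(pressure_bar = as.numeric(pressure),
                   temperature_K = as.numeric(temperature),
                   solubility_molefrac = as.numeric(solubility))
  validate_solubility_dataset(ds)
  attr(ds, "name") <- as.character(name)[1L]
  class(ds) <- c("solubility_dataset", "data.frame")
  ds
}

validate_solubility_dataset <- function(ds) {
  for (col in c("pressure_bar", "temperature_K", "solubility_molefrac")) {
    bad <- which(!is.finite(ds[[col]]))
    if (length(bad))
      stop(sprintf("missing or non-numeric value in column '%s' at row %d",
                   col, bad[1L]), call. = FALSE)
  }
  bad <- which(ds$pressure_bar <= 0)
  if (length(bad))
    stop(sprintf("non-positive pressure at row %d", bad[1L]), call. = FALSE)
  bad <- which(ds$temperature_K <= 0)
  if (length(bad))
    stop(sprintf("non-positive temperature at row %d", bad[1L]), call. = FALSE)
  bad <- which(ds$solubility_molefrac <= 0 | ds$solubility_molefrac >= 1)
  if (length(bad))
    stop(sprintf("solubility outside (0, 1) at row %d", bad[1L]),
         call. = FALSE)
  dup <- duplicated(ds[, c("pressure_bar", "temperature_K")])
  if (any(dup))
    stop(sprintf("duplicate (pressure, temperature) pair at row %d",
                 which(dup)[1L]), call. = FALSE)
  invisible(ds)
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat(sprintf("<solubility_dataset> '%s': %d records\n",
              attr(x, "name"), nrow(x)))
  cat(sprintf("  P: %g-%g bar, T: %g-%g K, y: %.3g-%.3g\n",
              min(x$pressure_bar), max(x$pressure_bar),
              min(x$temperature_K), max(x$temperature_K),
              min(x$solubility_molefrac), max(x$solubility_molefrac)))
  invisible(x)
}

#' Read a solubility dataset from CSV
#'
#' The canonical on-disk format is a CSV with header
#' `pressure_bar,temperature_K,solubility_molefrac`; scientific notation is
#' accepted. Other column names can be mapped via `dialect`.
#'
#' @param path path to a CSV file.
#' @param dialect optional named character vector mapping the canonical
#'   column names (`pressure_bar`, `temperature_K`, `solubility_molefrac`)
#'   to the names used in the file.
#' @param name dataset label; defaults to the file name.
#' @return A [solubility_dataset].
#' @export
read_solubility_csv <- function(path, dialect = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("no records", call. = FALSE))
  if (nrow(raw) == 0L) stop("no records", call. = FALSE)
  canon <- c("pressure_bar", "temperature_K", "solubility_molefrac")
  cols <- stats::setNames(canon, canon)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols))
    stop("cannot resolve column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  solubility_dataset(raw[[cols["pressure_bar"]]],
                     raw[[cols["temperature_K"]]],
                     raw[[cols["solubility_molefrac"]]],
                     name = name)
}

#' Write a solubility dataset to CSV
#'
#' Writes the canonical three-column CSV. Values are formatted with enough
#' digits (R's default 15 significant digits) that a read-back reproduces
#' the stored doubles exactly.
#'
#' @param ds a [solubility_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solubility_csv <- function(ds, path) {
  stopifnot(inherits(ds, "solubility_dataset"))
  df <- as.data.frame(ds)
  df$solubility_molefrac <- format(df$solubility_molefrac, digits = 15,
                                   trim = TRUE, scientific = NA)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled decitabine / SC-CO2 solubility dataset
#'
#' Thirty-two equilibrium solubility measurements of decitabine in
#' supercritical carbon dioxide on a full factorial grid of eight pressures
#' (120-400 bar in 40-bar steps) and four temperatures (308-338 K in 10-K
#' steps). Solubility spans 2.84e-5 to 1.07e-3 mole fraction, with the
#' maximum at 400 bar, 338 K.
#'
#' @return A [solubility_dataset] with 32 records.
#' @examples
#' ds <- decitabine_dataset()
#' nrow(ds)
#' @export
decitabine_dataset <- function() {
  path <- system.file("extdata", "decitabine_scco2.csv", package = "scsolub",
                      mustWork = TRUE)
  read_solubility_csv(path, name = "decitabine / SC-CO2")
}

#' Random train/test split of a solubility dataset
#'
#' Partitions the records into disjoint train and test subsets,
#' reproducibly for a fixed seed. The number of test records is
#' `round(n * test_fraction)`.
#'
#' @param ds a [solubility_dataset].
#' @param test_fraction fraction of records assigned to the test set,
#'   in (0, 1). Default 0.25.
#' @param seed integer seed controlling the assignment.
#' @return A list with elements `train` and `test`, both
#'   [solubility_dataset]s.
#' @export
split_dataset <- function(ds, test_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(ds, "solubility_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(ds)
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n - n_test < 1L)
    stop("split would leave an empty train or test set", call. = FALSE)
  idx <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    sample.int(n, n_test)
  })
  nm <- attr(ds, "name")
  list(
    train = solubility_dataset(ds$pressure_bar[-idx], ds$temperature_K[-idx],
                               ds$solubility_molefrac[-idx],
                               name = paste(nm, "(train)")),
    test = solubility_dataset(ds$pressure_bar[idx], ds$temperature_K[idx],
                              ds$solubility_molefrac[idx],
                              name = paste(nm, "(test)"))
  )
}
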