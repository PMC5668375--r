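#' Model parameters for the BCR survival-signal model
#'
#' Bundles the eight rate and threshold constants of the integrated tonic +
#' antigen-triggered survival-signal model. Units: time in hours, antibody
#' dose in ug/ml, BCR levels and signals dimensionless on \[0, 1\].
#'
#' @param d1 BCR degradation rate (/h).
#' @param k1 Tonic signal generation rate (/h), driven by free BCR.
#' @param k2 Antibody-BCR association rate (ml/ug/h).
#' @param k3 Antibody-BCR dissociation rate (/h).
#' @param k4 Crosslinked-BCR signal generation rate (/h).
#' @param d2 Signal consumption rate (/h).
#' @param offset Activation threshold: the fraction of total BCR that must be
#'   crosslinked before the antigen-triggered term produces any effective
#'   signal (dimensionless, in \[0, 1\]).
#' @param deadline Survival-signal death threshold: a cell dies when
#'   `signal_on` drops below this value (dimensionless, in \[0, 1\]).
#'
#' @return An object of class `bcr_params`: a named list with the eight
#'   constants, validated (all non-negative; `offset` and `deadline` in
#'   \[0, 1\]).
#' @examples
#' p <- bcr_params_table1()
#' p$k3 / p$k2
#' @export
bcr_params <- function(d1, k1, k2, k3, k4, d2, offset, deadline) {
  p <- list(d1 = d1, k1 = k1, k2 = k2, k3 = k3, k4 = k4, d2 = d2,
            offset = offset, deadline = deadline)
  validate_bcr_params(p)
}

validate_bcr_params <- function(p) {
  nm <- c("d1", "k1", "k2", "k3", "k4", "d2", "offset", "deadline")
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    abort(paste0("missing model parameter(s): ", paste(missing, collapse = ", ")))
  }
  p <- p[nm]
  vals <- vapply(p, function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(vals))) abort("all model parameters must be finite numbers")
  if (any(vals < 0)) abort("all model parameters must be non-negative")
  if (vals[["offset"]] > 1) abort("`offset` must lie in [0, 1]")
  if (vals[["deadline"]] > 1) abort("`deadline` must lie in [0, 1]")
  structure(as.list(vals), class = "bcr_params")
}

#' @export
print.bcr_params <- function(x, ...) {
  cat("<bcr_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @describeIn bcr_params Coerce to a one-row tibble.
#' @param x A `bcr_params` object.
#' @param ... Unused.
#' @export
as_tibble.bcr_params <- function(x, ...) {
  tibble::as_tibble(as.list(unclass(x)))
}

# fixed order used by the C++ integrator
params_vec <- function(p) {
  unlist(p[c("d1", "k1", "k2", "k3", "k4", "d2", "offset", "deadline")])
}

#' Packaged parameter sets
#'
#' `bcr_params_table1()` returns the consensus fitted parameter set of the
#' full (tonic + antigen-triggered) model; `bcr_params_first_stage()` returns
#' the tonic-only fit obtained from unstimulated survival data (its `k4` and
#' `offset` are zero since the antigen-triggered branch is absent at dose 0).
#' The two fits disagree slightly on `k1`, `d2` and `deadline`; both are kept.
#'
#' @return A [bcr_params] object.
#' @examples
#' bcr_params_table1()
#' @export
bcr_params_table1 <- function() {
  read_bcr_params(system.file("extdata", "params_table1.json",
                              package = "bcrsurv", mustWork = TRUE))
}

#' @rdname bcr_params_table1
#' @export
bcr_params_first_stage <- function() {
  read_bcr_params(system.file("extdata", "params_first_stage.json",
                              package = "bcrsurv", mustWork = TRUE))
}

#' Read or write a parameter set as flat JSON
#'
#' Parameter files are flat JSON objects keyed `d1, k1, k2, k3, k4, d2,
#' offset, deadline`. Unknown keys are ignored with a warning; missing keys
#' are an error naming the key.
#'
#' @param path File path.
#' @return `read_bcr_params()` returns a [bcr_params]; `write_bcr_params()`
#'   returns `path` invisibly.
#' @export
read_bcr_params <- function(path) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("d1", "k1", "k2", "k3", "k4", "d2", "offset", "deadline")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warn(paste0("ignoring unknown parameter key(s): ", paste(extra, collapse = ", ")))
  }
  validate_bcr_params(raw[intersect(names(raw), known)])
}

#' @rdname read_bcr_params
#' @param params A [bcr_params] object.
#' @export
write_bcr_params <- function(params, path) {
  params <- validate_bcr_params(params)
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
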