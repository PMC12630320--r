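# Synthetic paired/blocked samples from the catalog models, plus the
# delimited-table interface (block_id, arm, value [, x]).

#' Sample blocked outcomes from a catalog model
#'
#' Draws `b` independent blocks from `model`. Nuisance parameters are fixed
#' per-block constants: supply them directly, or give a generating rule that
#' is applied once (a sampling convenience; the values are then treated as
#' fixed and recorded in the metadata).
#'
#' @param model An `ft_model` from [make_model()].
#' @param b Number of blocks (or units, for the block-size-1 regression
#'   models).
#' @param psi Interest parameter value(s), in the order of `model$interest`.
#' @param nuisance Per-block nuisance values: a scalar (recycled), a numeric
#'   vector of length `b`, a function `f(b)` returning such a vector, or a
#'   list `list(kind = "fixed", values = ...)` /
#'   `list(kind = "lognormal", meanlog = , sdlog = )`. For
#'   `exp_mean_shift_pair`, `list(kind = "mu", values = ...)` supplies the
#'   pair means `mu_i`, converted via `lambda_i = 1/mu_i`.
#' @param shared Named list of shared parameter values (e.g. `alpha`, `beta`).
#' @param seed Integer seed; identical seeds give identical samples.
#' @param x Optional covariate vector for the regression models.
#' @param format `"long"` (default) returns a data frame with columns
#'   `block_id`, `arm`, `value` (plus `x` for covariate models); `"wide"`
#'   returns the b-by-m outcome matrix.
#' @return A data frame (or matrix) with attributes `model`, `psi`,
#'   `nuisance`, `shared`, `seed`.
#' @examples
#' m <- make_model("exp_hazard_pair")
#' d <- sample_blocks(m, b = 4, psi = 2, nuisance = 1, seed = 1)
#' head(d)
#' @export
sample_blocks <- function(model, b, psi = NULL, nuisance = 1, shared = list(),
                          seed = 1, x = NULL, format = c("long", "wide")) {
  format <- match.arg(format)
  if (b < 0 || b != round(b)) stop("b must be a nonnegative integer", call. = FALSE)
  lam <- resolve_nuisance(nuisance, b, seed)
  if (identical(attr(lam, "parameterisation"), "mu")) {
    if (model$name != "exp_mean_shift_pair")
      stop("'mu' parameterisation only applies to exp_mean_shift_pair", call. = FALSE)
    lam <- 1 / as.numeric(lam)
  }
  params <- resolve_params(model, psi = psi, nuisance = as.numeric(lam),
                           shared = shared)
  set.seed(seed)
  mat <- if (b == 0) {
    matrix(numeric(0), 0, length(model$arms), dimnames = list(NULL, model$arms))
  } else {
    model$sampler(b, params, x = x)
  }
  xs <- attr(mat, "x")
  meta <- list(model = model$name, psi = params[model$interest],
               nuisance = as.numeric(lam), shared = params[model$shared],
               seed = seed)
  if (format == "wide") {
    attributes(mat) <- c(attributes(mat), meta)
    return(mat)
  }
  arms <- colnames(mat) %||% model$arms
  out <- data.frame(
    block_id = rep(seq_len(max(b, 0)), times = length(arms)),
    arm = rep(arms, each = b),
    value = as.vector(mat))
  if (!is.null(xs)) out$x <- rep(xs, length(arms))
  out <- out[order(out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out), meta)
  class(out) <- c("ft_sample", "data.frame")
  out
}

# Turn the accepted nuisance specifications into a fixed numeric vector.
resolve_nuisance <- function(nuisance, b, seed) {
  if (is.function(nuisance)) return(nuisance(b))
  if (is.numeric(nuisance)) {
    if (!length(nuisance) %in% c(1L, b) && b > 0)
      stop("nuisance vector must have length 1 or b", call. = FALSE)
    return(rep_len(nuisance, b))
  }
  if (is.list(nuisance)) {
    kind <- nuisance$kind %||% "fixed"
    if (kind %in% c("fixed", "mu")) {
      v <- rep_len(nuisance$values, b)
      if (kind == "mu") attr(v, "parameterisation") <- "mu"
      return(v)
    }
    if (kind == "lognormal") {
      set.seed(seed + 1L)
      return(stats::rlnorm(b, nuisance$meanlog %||% 0, nuisance$sdlog %||% 0.5))
    }
    stop("unknown nuisance kind: ", kind, call. = FALSE)
  }
  stop("invalid nuisance specification", call. = FALSE)
}

#' Blocked sample as a wide matrix
#'
#' @param data A long-format sample (from [sample_blocks()] or
#'   [read_blocks()]), or an already-wide matrix (returned unchanged).
#' @param arms Canonical arm order; defaults to the order of appearance with
#'   `"T"` before `"C"` when both occur.
#' @return Numeric b-by-m matrix with one column per arm.
#' @export
block_matrix <- function(data, arms = NULL) {
  if (is.matrix(data)) return(data)
  stopifnot(is.data.frame(data), all(c("block_id", "arm", "value") %in% names(data)))
  present <- unique(as.character(data$arm))
  if (is.null(arms)) {
    arms <- if (setequal(present, c("T", "C"))) c("T", "C") else sort(present)
  }
  ids <- sort(unique(data$block_id))
  out <- matrix(NA_real_, length(ids), length(arms),
                dimnames = list(NULL, arms))
  for (j in seq_along(arms)) {
    sub <- data[data$arm == arms[j], ]
    if (anyDuplicated(sub$block_id))
      stop("block ", sub$block_id[duplicated(sub$block_id)][1],
           " has more than one row for arm ", arms[j], call. = FALSE)
    out[match(sub$block_id, ids), j] <- sub$value
  }
  if (anyNA(out)) stop("every block needs exactly one row per arm", call. = FALSE)
  out
}

#' Read a blocked outcome table
#'
#' Reads a comma- or tab-delimited file with header
#' `block_id,arm,value[,x...]`.
#'
#' @param file Path to the table.
#' @return Long-format data frame.
#' @export
read_blocks <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file, call. = FALSE)
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("block_id", "arm", "value")
  if (!all(need %in% names(d)))
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Write a blocked outcome table
#'
#' @param data Long-format sample.
#' @param file Output path.
#' @param sep Field separator (`","` or `"\t"`).
#' @export
write_blocks <- function(data, file, sep = ",") {
  utils::write.table(as.data.frame(data), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
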