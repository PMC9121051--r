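#' Quadrature sum
#'
#' Combines independent uncertainty magnitudes as the square root of the sum
#' of squares, \eqn{\sqrt{\sum v_i^2}}, the ICRU-recommended rule for
#' uncorrelated, normally distributed error components.  Sign-agnostic:
#' signed per-axis means enter via their squares and the result is always
#' non-negative and at least \code{max(abs(values))}.
#'
#' @param values numeric vector of component magnitudes (signed values
#'   allowed).  Absent (NA) entries must be excluded by the caller.
#' @return scalar, \code{sqrt(sum(values^2))}.
#' @examples
#' quadrature(c(0.45, 0.72))  # 0.849
#' @export
quadrature <- function(values) {
  if (length(values) == 0L)
    stop_iconqa("quadrature() needs at least one value", "iconqa_validation_error")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_iconqa("quadrature() values must be finite numbers", "iconqa_validation_error")
  sqrt(sum(values^2))
}

#' Per-measurement vector mean and SD
#'
#' The "total vector mean" convention used throughout the uncertainty
#' budget: the mean (and sample SD) of the per-measurement Euclidean
#' displacement norms -- \emph{not} the norm of the per-axis means.  By the
#' triangle inequality the former is always at least the latter.
#'
#' @param vectors an n x 3 numeric matrix (or data.frame), one displacement
#'   vector per row, in mm.
#' @return list with \code{mean}, \code{sd} (0 when \code{n == 1}, flagged
#'   by \code{sd_defined = FALSE}) and \code{n}.
#' @examples
#' vector_mean(rbind(c(3, 4, 0)))          # mean 5, n = 1
#' vector_mean(rbind(c(1, 0, 0), c(0, 1, 0)))  # mean 1, sd 0
#' @export
vector_mean <- function(vectors) {
  m <- as.matrix(vectors)
  if (nrow(m) == 0L)
    stop_iconqa("vector_mean() needs at least one vector", "iconqa_validation_error")
  if (ncol(m) != 3L || any(!is.finite(m)))
    stop_iconqa("vector_mean() expects an n x 3 finite matrix", "iconqa_validation_error")
  norms <- sqrt(rowSums(m^2))
  n <- length(norms)
  list(mean = mean(norms),
       sd = if (n > 1L) stats::sd(norms) else 0,
       sd_defined = n > 1L,
       n = n)
}

#' Construct an uncertainty component row
#'
#' One row of a component table: per-axis signed means and SDs (any axis may
#' be absent, e.g. a radial-only QA readout), the per-measurement vector
#' mean/SD, the measurement count, the systematic/random classification used
#' by margin recipes, and the Type A (own repeated measurements) / Type B
#' (external or published source) provenance class.
#'
#' @param name component label.
#' @param axis_mean,axis_sd length-3 numeric (x, y, z) in mm; NA = absent.
#' @param vec_mean,vec_sd per-measurement vector mean and SD in mm
#'   (\code{vec_mean >= 0}).
#' @param n number of measurements (NA if unknown).
#' @param error_type \code{"systematic"} or \code{"random"}.
#' @param class \code{"A"} or \code{"B"}.
#' @return one-row data.frame of class \code{component_table}.
#' @export
uncertainty_component <- function(name,
                                  axis_mean = c(NA, NA, NA),
                                  axis_sd = c(NA, NA, NA),
                                  vec_mean, vec_sd = NA, n = NA,
                                  error_type = c("systematic", "random"),
                                  class = c("A", "B")) {
  error_type <- match.arg(error_type)
  class <- match.arg(class)
  stopifnot(length(axis_mean) == 3L, length(axis_sd) == 3L)
  if (!is.na(vec_mean) && vec_mean < 0)
    stop_iconqa("vector mean must be >= 0", "iconqa_validation_error")
  sds <- c(axis_sd, vec_sd)
  if (any(sds < 0, na.rm = TRUE))
    stop_iconqa("standard deviations must be >= 0", "iconqa_validation_error")
  out <- data.frame(
    name = as.character(name),
    x_mean = as.numeric(axis_mean[1]), x_sd = as.numeric(axis_sd[1]),
    y_mean = as.numeric(axis_mean[2]), y_sd = as.numeric(axis_sd[2]),
    z_mean = as.numeric(axis_mean[3]), z_sd = as.numeric(axis_sd[3]),
    vec_mean = as.numeric(vec_mean), vec_sd = as.numeric(vec_sd),
    n = as.numeric(n),
    error_type = error_type, class = class,
    stringsAsFactors = FALSE)
  class(out) <- c("component_table", "data.frame")
  out
}

component_table_columns <- c("name", "x_mean", "x_sd", "y_mean", "y_sd",
                             "z_mean", "z_sd", "vec_mean", "vec_sd", "n",
                             "error_type", "class")

as_component_table <- function(df) {
  missing_cols <- setdiff(component_table_columns, names(df))
  if (length(missing_cols))
    stop_iconqa(paste("component table missing columns:",
                      paste(missing_cols, collapse = ", ")),
                "iconqa_validation_error")
  df <- df[component_table_columns]
  if (!all(df$error_type %in% c("systematic", "random", "combined")))
    stop_iconqa("error_type must be 'systematic', 'random' or 'combined'",
                "iconqa_validation_error")
  class(df) <- c("component_table", "data.frame")
  df
}

#' Combine uncertainty components in quadrature
#'
#' Builds a totals row from a component table: per-axis means are the
#' quadrature of the component per-axis means, per-axis SDs the quadrature
#' of the per-axis SDs, and the vector mean the quadrature of the component
#' vector means.  Absent (NA) axis entries -- e.g. a stability test that
#' reads out radially only -- are excluded, not treated as zero.  The vector
#' SD of a total is not derivable from component summaries alone and is
#' reported as NA.
#'
#' @param components a \code{component_table}.
#' @param filter \code{"all"}, \code{"systematic"} or \code{"random"}.
#' @return one-row \code{component_table} totals row.  Quadrature is
#'   associative, so the \code{"all"} row equals the quadrature of the
#'   systematic and random rows.
#' @export
combine_components <- function(components,
                               filter = c("all", "systematic", "random")) {
  filter <- match.arg(filter)
  components <- as_component_table(components)
  if (filter != "all")
    components <- components[components$error_type == filter, , drop = FALSE]
  if (nrow(components) == 0L)
    stop_iconqa(paste0("no components with error_type '", filter, "'"),
                "iconqa_validation_error")
  quad_col <- function(col) {
    v <- components[[col]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else quadrature(v)
  }
  label <- switch(filter,
                  systematic = "Total systematic",
                  random = "Total random",
                  all = "Total uncertainty")
  out <- uncertainty_component(
    name = label,
    axis_mean = c(quad_col("x_mean"), quad_col("y_mean"), quad_col("z_mean")),
    axis_sd = c(quad_col("x_sd"), quad_col("y_sd"), quad_col("z_sd")),
    vec_mean = quad_col("vec_mean"),
    vec_sd = NA,
    n = sum(components$n, na.rm = TRUE),
    error_type = if (filter == "random") "random" else "systematic",
    class = "A")
  out$error_type <- switch(filter, systematic = "systematic",
                           random = "random", all = "combined")
  out
}

#' Assemble an uncertainty budget
#'
#' Classifies components and computes the three quadrature totals rows
#' (systematic, random, combined).
#'
#' @param components a \code{component_table} with at least one systematic
#'   and one random component (a missing stratum is allowed; its totals row
#'   is then omitted).
#' @return object of class \code{uncertainty_budget}: list with
#'   \code{components} and \code{totals} (both \code{component_table}s).
#' @export
uncertainty_budget <- function(components) {
  components <- as_component_table(components)
  if (nrow(components) == 0L)
    stop_iconqa("empty component table", "iconqa_validation_error")
  strata <- intersect(c("systematic", "random"), unique(components$error_type))
  totals <- do.call(rbind, c(
    lapply(strata, function(s) combine_components(components, s)),
    list(combine_components(components, "all"))))
  totals <- as_component_table(totals)
  structure(list(components = components, totals = totals),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("Uncertainty budget:", nrow(x$components), "components\n")
  cat(render_report(x, format = "markdown"), sep = "\n")
  invisible(x)
}

#' Probability that total displacement falls below a threshold
#'
#' Assuming the total vector uncertainty is normally distributed with the
#' given mean and SD, returns \eqn{\Phi((threshold - mean)/sd)}.  With
#' \code{sd = 0} the distribution is degenerate at the mean and the result
#' is the step function (1 when \code{threshold >= mean}, else 0).
#'
#' @param threshold_mm,mean_mm,sd_mm mm; \code{sd_mm >= 0}.
#' @return probability in [0, 1].
#' @examples
#' prob_below(1.00, 1.30, 0.51)  # ~0.278
#' @export
prob_below <- function(threshold_mm, mean_mm, sd_mm) {
  if (!is.finite(sd_mm) || sd_mm < 0)
    stop_iconqa("sd_mm must be a finite non-negative number",
                "iconqa_validation_error")
  if (sd_mm == 0) return(as.numeric(threshold_mm >= mean_mm))
  stats::pnorm((threshold_mm - mean_mm) / sd_mm)
}

#' Literature setup-margin recipes
#'
#' Converts the systematic SD (\eqn{\Sigma}) and random SD (\eqn{\sigma}) of
#' a setup-error distribution into a clinical setup margin:
#' van Herk \eqn{2.5\Sigma + 0.7\sigma} (covers 90\% of patients with 95\%
#' of the prescribed minimum dose) or Stroom \eqn{2.0\Sigma + 0.7\sigma}.
#' Vectorised over \code{Sigma_mm}/\code{sigma_mm} so per-axis margins come
#' from per-axis SDs.
#'
#' @param recipe \code{"vanherk"} or \code{"stroom"}.
#' @param Sigma_mm systematic SD(s) in mm, >= 0.
#' @param sigma_mm random SD(s) in mm, >= 0.
#' @return object of class \code{margin_result}: list with \code{recipe},
#'   \code{margin_mm}, and the inputs.
#' @examples
#' setup_margin("vanherk", 0.5, 0.3)  # 1.46 mm
#' @export
setup_margin <- function(recipe = c("vanherk", "stroom"), Sigma_mm, sigma_mm) {
  recipe <- match.arg(recipe)
  if (any(Sigma_mm < 0) || any(sigma_mm < 0))
    stop_iconqa("Sigma_mm and sigma_mm must be >= 0", "iconqa_validation_error")
  k <- margin_coefficients[[recipe]]
  structure(list(recipe = recipe,
                 margin_mm = k[["Sigma"]] * Sigma_mm + k[["sigma"]] * sigma_mm,
                 Sigma_mm = Sigma_mm, sigma_mm = sigma_mm),
            class = "margin_result")
}

# margin recipe coefficients (configurable constants, not buried in code)
margin_coefficients <- list(
  vanherk = c(Sigma = 2.5, sigma = 0.7),
  stroom  = c(Sigma = 2.0, sigma = 0.7))

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("Setup margin (%s): %s mm  [Sigma = %s, sigma = %s]\n",
              x$recipe, paste(round_half_up(x$margin_mm), collapse = ", "),
              paste(x$Sigma_mm, collapse = ", "),
              paste(x$sigma_mm, collapse = ", ")))
  invisible(x)
}

#' Read / write a component table CSV
#'
#' Columns \code{name, x_mean, x_sd, y_mean, y_sd, z_mean, z_sd, vec_mean,
#' vec_sd, n, error_type, class}; an empty cell means the entry is absent
#' (excluded from quadrature), never zero.
#'
#' @param path CSV file path.
#' @return \code{read_component_table}: a \code{component_table}.
#' @export
read_component_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_component_table(df)
}

#' @rdname read_component_table
#' @param components a \code{component_table} to write.
#' @export
write_component_table <- function(components, path) {
  components <- as_component_table(components)
  utils::write.csv(components, path, row.names = FALSE, na = "")
  invisible(path)
}
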