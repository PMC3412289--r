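#' Response-model contract: from active synapses to a binary spike decision
#'
#' A response model converts the set of active synapse slots of one
#' postsynaptic cell into a binary decision — spike / no spike — within one
#' gamma window (~20 ms). [respond()] and [population_response()] are S3
#' generics so that alternative neuron backends can be plugged in behind the
#' same contract. Any backend must be:
#'
#' * **deterministic**: a frozen model instance maps identical
#'   `(cell, active slots)` to the same decision every time;
#' * **binary**: the decision is 0 or 1 per cell per window; all temporal
#'   structure inside the window is abstracted away.
#'
#' @section Adapter contract for a compartmental backend:
#' A detailed biophysical backend (multi-compartment CA1 cell with
#' conductance-based synapses) satisfies the contract by: activating the
#' AMPA/GABAa synapses of the listed slots simultaneously at t = 0,
#' integrating the cell for at most 20 ms, and returning 1 iff the somatic
#' membrane potential reaches the 10 mV action-potential threshold within
#' the window, with every cell reset to the same initial state at t = 0
#' (the gamma reset). Such a backend is not shipped here; the package ships
#' [threshold_surrogate()].
#'
#' @param model A response model object.
#' @param ... Method arguments; see [respond.threshold_surrogate()].
#' @return `respond()`: integer 0 or 1. `population_response()`: a
#'   [binary_pattern()] of length `n_post`.
#' @name response_model
NULL

#' @rdname response_model
#' @export
respond <- function(model, ...) UseMethod("respond")

#' @rdname response_model
#' @export
population_response <- function(model, ...) UseMethod("population_response")

#' Random-weight threshold surrogate neuron
#'
#' A deterministic stand-in for a detailed compartmental neuron: each synapse
#' slot of each cell carries a fixed positive weight drawn once at
#' construction, and a cell spikes in a window iff the summed weight of its
#' active slots reaches the firing threshold `theta` (in dimensionless drive
#' units). Weights are frozen after construction — the model is stateless
#' across gamma windows — and the decision is monotone: activating additional
#' excitatory slots can never veto a spike.
#'
#' Weight heterogeneity is essential: with equal weights, all cells with
#' equal active-synapse counts would decide identically and the population
#' would carry no cell-identity information. The default is i.i.d. lognormal
#' weights (`meanlog = 0`, `sdlog = 0.5`), a standard description of
#' excitatory synaptic efficacies; `"constant"` and `"uniform"` options are
#' provided for sensitivity analysis and for exact arithmetic in tests.
#'
#' Feedforward inhibition is not modeled as negative input; its effect on the
#' operating point is absorbed into `theta`, which is set by
#' [calibrate_threshold()] to reach the target population spiking
#' probability.
#'
#' @param maps Named list of [build_projection()] maps, one per pathway
#'   (e.g. `list(CA3 = ..., EC = ...)`), all with the same `n_post`.
#' @param theta Firing threshold, strictly positive.
#' @param weight_distribution `"lognormal"`, `"constant"` or `"uniform"`.
#' @param weight_params Distribution parameters: `meanlog`/`sdlog`
#'   (lognormal), `value` (constant), `min`/`max` (uniform, both > 0).
#' @param seed Optional integer seed for the weight draw; stored for
#'   regeneration.
#' @return Object of class `threshold_surrogate`: `maps`, `weights` (named
#'   list of matrices matching each map's `pre`), `theta`,
#'   `weight_distribution`, `weight_params`, `seed`, `n_post`.
#' @export
threshold_surrogate <- function(maps, theta = 1,
                                weight_distribution = c("lognormal",
                                                        "constant",
                                                        "uniform"),
                                weight_params = NULL, seed = NULL) {
  weight_distribution <- match.arg(weight_distribution)
  stopifnot(is.list(maps), length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "projection_map")))
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, function(m) m$spec$name, character(1))
  }
  n_post <- unique(vapply(maps, function(m) m$n_post, integer(1)))
  if (length(n_post) != 1) stop("all pathway maps must share n_post")
  weight_params <- .weight_params(weight_distribution, weight_params)
  weights <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    nw <- length(m$pre)
    w <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, names(maps)[i]),
      switch(weight_distribution,
        lognormal = stats::rlnorm(nw, weight_params$meanlog,
                                  weight_params$sdlog),
        constant = rep(weight_params$value, nw),
        uniform = stats::runif(nw, weight_params$min, weight_params$max)
      )
    )
    matrix(w, nrow = m$n_post)
  })
  names(weights) <- names(maps)
  .check_theta(theta)
  structure(
    list(maps = maps, weights = weights, theta = theta,
         weight_distribution = weight_distribution,
         weight_params = weight_params,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         n_post = n_post),
    class = "threshold_surrogate"
  )
}

.weight_params <- function(dist, params) {
  defaults <- switch(dist,
    lognormal = list(meanlog = 0, sdlog = 0.5),
    constant = list(value = 1),
    uniform = list(min = 0.5, max = 1.5)
  )
  params <- utils::modifyList(defaults, as.list(params %||% list()))
  if (dist == "constant" && params$value <= 0) {
    stop("constant weight must be positive")
  }
  if (dist == "uniform" && (params$min <= 0 || params$max <= params$min)) {
    stop("uniform weights need 0 < min < max")
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_theta <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, !is.na(theta))
  if (theta <= 0) stop("theta must be strictly positive (a cell needs excitatory drive to fire)")
  invisible(theta)
}

#' Set the firing threshold of a threshold surrogate
#'
#' @param model A [threshold_surrogate()].
#' @param theta New threshold, strictly positive.
#' @return The model with `theta` replaced (weights untouched).
#' @export
set_theta <- function(model, theta) {
  stopifnot(inherits(model, "threshold_surrogate"))
  .check_theta(theta)
  model$theta <- theta
  model
}

#' @export
print.threshold_surrogate <- function(x, ...) {
  cat(sprintf(
    "<threshold_surrogate> %d cells, pathways: %s; theta = %.4g, %s weights\n",
    x$n_post, paste(names(x$maps), collapse = " + "), x$theta,
    x$weight_distribution))
  invisible(x)
}

#' Single-cell spike decision of the threshold surrogate
#'
#' Sums the frozen weights of the listed active slots across pathways and
#' compares against `theta`.
#'
#' @param model A [threshold_surrogate()].
#' @param cell_id Postsynaptic cell index in `1:n_post`.
#' @param active_slots_by_pathway Named list, per pathway, of active slot
#'   indices (in `1:synapses_per_post`); pathways may be omitted
#'   (treated as silent).
#' @param ... Unused.
#' @return Integer 0 or 1.
#' @export
respond.threshold_surrogate <- function(model, cell_id,
                                        active_slots_by_pathway, ...) {
  stopifnot(is_count(cell_id, 1))
  if (cell_id > model$n_post) {
    stop(sprintf("unknown cell %d (n_post = %d)", cell_id, model$n_post))
  }
  drive <- 0
  for (pw in names(active_slots_by_pathway)) {
    if (!pw %in% names(model$maps)) stop(sprintf("unknown pathway '%s'", pw))
    slots <- as.integer(active_slots_by_pathway[[pw]])
    s_max <- model$maps[[pw]]$spec$synapses_per_post
    if (length(slots) > 0 && (min(slots) < 1 || max(slots) > s_max)) {
      stop(sprintf("slot out of range for pathway '%s'", pw))
    }
    drive <- drive + sum(model$weights[[pw]][cell_id, slots])
  }
  as.integer(drive >= model$theta)
}

# Summed synaptic drive per postsynaptic cell for the given inputs
# (named list of binary_pattern per driven pathway).
.population_drive <- function(model, inputs) {
  stopifnot(is.list(inputs), length(inputs) >= 1)
  if (is.null(names(inputs)) || any(!names(inputs) %in% names(model$maps))) {
    stop("inputs must be a named list keyed by pathway name")
  }
  drive <- numeric(model$n_post)
  for (pw in names(inputs)) {
    map <- model$maps[[pw]]
    inp <- inputs[[pw]]
    stopifnot(is_binary_pattern(inp))
    if (inp$length != map$spec$n_pre) {
      stop(sprintf("input length %d does not match n_pre %d of pathway '%s'",
                   inp$length, map$spec$n_pre, pw))
    }
    drive <- drive + rowSums(model$weights[[pw]] * .active_matrix(map, inp))
  }
  drive
}

#' Population response of the threshold surrogate
#'
#' Applies the spike rule to every cell of the patch for one or more driven
#' pathways and returns the binary CA1 output pattern for the window.
#'
#' @param model A [threshold_surrogate()].
#' @param inputs Named list of [binary_pattern()] inputs keyed by pathway
#'   name; pathways not listed are silent.
#' @param ... Unused.
#' @return A [binary_pattern()] of length `n_post`.
#' @export
population_response.threshold_surrogate <- function(model, inputs, ...) {
  drive <- .population_drive(model, inputs)
  binary_pattern(model$n_post, which(drive >= model$theta))
}

# ---- model state file ---------------------------------------------------

#' Save and restore a threshold surrogate
#'
#' The state file is JSON holding the distribution name, parameters, theta
#' and the weight seed; weights are regenerated from the seed at load time
#' rather than stored, so the file is small and plain text. Loading requires
#' the same projection maps the model was built on (their identity is
#' checked via pathway names and dimensions).
#'
#' @param model A [threshold_surrogate()] built with a non-`NULL` seed.
#' @param path JSON path.
#' @param maps The projection maps to rebind on load.
#' @return `write_response_model()` returns `path` invisibly;
#'   `read_response_model()` returns a `threshold_surrogate`.
#' @export
write_response_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_surrogate"))
  if (is.na(model$seed)) {
    stop("model has no seed: weights cannot be regenerated from a state file")
  }
  state <- list(
    class = "threshold_surrogate",
    weight_distribution = model$weight_distribution,
    weight_params = model$weight_params,
    theta = model$theta,
    seed = model$seed,
    pathways = lapply(model$maps, function(m) {
      list(name = m$spec$name, n_pre = m$spec$n_pre,
           synapses_per_post = m$spec$synapses_per_post,
           n_post = m$n_post)
    })
  )
  jsonlite::write_json(state, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_response_model
#' @export
read_response_model <- function(path, maps) {
  state <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (pw in names(state$pathways)) {
    ref <- state$pathways[[pw]]
    if (!pw %in% names(maps)) stop(sprintf("missing pathway map '%s'", pw))
    m <- maps[[pw]]
    if (m$spec$n_pre != ref$n_pre ||
        m$spec$synapses_per_post != ref$synapses_per_post ||
        m$n_post != ref$n_post) {
      stop(sprintf("map '%s' does not match the saved model dimensions", pw))
    }
  }
  threshold_surrogate(
    maps,
    theta = state$theta,
    weight_distribution = state$weight_distribution,
    weight_params = state$weight_params,
    seed = state$seed
  )
}
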