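#' Feedforward pathway specification
#'
#' Describes one excitatory feedforward pathway onto the CA1 patch: the
#' presynaptic population size, the number of synapse slots each postsynaptic
#' cell devotes to the pathway, and the mean number of postsynaptic targets
#' per presynaptic cell (fan-out, or divergence). The three numbers are tied
#' by edge counting: `n_pre * fanout` and `n_post * synapses_per_post` count
#' the same synapses, so they must agree to within rounding (one unit per
#' postsynaptic cell) — checked by [build_projection()].
#'
#' Reference (full-scale) values: the Schaffer-collateral pathway has
#' 28,009 CA3 cells onto 4407 slots per cell (fan-out 3697) and the
#' perforant path has 45,073 EC cells onto 1918 tuft slots per cell
#' (fan-out 1000), for a patch of 23,500 CA1 principal cells.
#'
#' @param name Pathway label, conventionally `"CA3"` or `"EC"`.
#' @param n_pre Presynaptic population size.
#' @param synapses_per_post Synapse slots per postsynaptic cell.
#' @param fanout Mean postsynaptic targets per presynaptic cell.
#' @return Object of class `pathway_spec`.
#' @examples
#' pathway_spec("EC", n_pre = 45073, synapses_per_post = 1918, fanout = 1000)
#' @export
pathway_spec <- function(name, n_pre, synapses_per_post, fanout) {
  stopifnot(is.character(name), length(name) == 1L,
            is_count(n_pre, 1), is_count(synapses_per_post, 1),
            is_count(fanout, 1))
  structure(
    list(name = name, n_pre = as.integer(n_pre),
         synapses_per_post = as.integer(synapses_per_post),
         fanout = as.integer(fanout)),
    class = "pathway_spec"
  )
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat(sprintf("<pathway_spec> %s: n_pre = %d, synapses/post = %d, fanout = %d\n",
              x$name, x$n_pre, x$synapses_per_post, x$fanout))
  invisible(x)
}

#' Presynaptic population size implied by patch size, slots and fan-out
#'
#' Edge counting: `n_post` cells with `synapses_per_post` slots each hold
#' `n_post * synapses_per_post` synapses; if each presynaptic cell accounts
#' for `fanout` of them, the presynaptic population is
#' `n_post * synapses_per_post / fanout`, rounded to the nearest integer.
#'
#' @param n_post Number of postsynaptic cells in the patch.
#' @param synapses_per_post Synapse slots per postsynaptic cell.
#' @param fanout Postsynaptic targets per presynaptic cell.
#' @return Integer presynaptic population size.
#' @examples
#' presyn_count(23500, 1918, 1000) # 45073
#' @export
presyn_count <- function(n_post, synapses_per_post, fanout) {
  stopifnot(is_count(n_post, 1), is_count(synapses_per_post, 1),
            is_count(fanout, 1))
  as.integer(round(n_post * synapses_per_post / fanout))
}

#' Fan-out implied by patch size, slots and presynaptic population
#'
#' The inverse of [presyn_count()]: with `n_post * synapses_per_post`
#' synapses shared among `n_pre` presynaptic cells, each contacts
#' `n_post * synapses_per_post / n_pre` postsynaptic cells on average,
#' reported as the whole number of complete targets (integer part; e.g.
#' 23,500 x 4407 / 28,009 = 3697.5 gives 3697).
#'
#' @inheritParams presyn_count
#' @param n_pre Presynaptic population size.
#' @return Integer mean fan-out.
#' @examples
#' fanout_of(23500, 4407, 28009) # 3697
#' fanout_of(23500, 1918, 45073) # 1000
#' @export
fanout_of <- function(n_post, synapses_per_post, n_pre) {
  stopifnot(is_count(n_post, 1), is_count(synapses_per_post, 1),
            is_count(n_pre, 1))
  as.integer(floor(n_post * synapses_per_post / n_pre + 1e-9))
}

#' Build a random feedforward projection map
#'
#' Wires each postsynaptic cell's `synapses_per_post` slots to presynaptic
#' cells chosen uniformly at random *without replacement* within the cell, so
#' each presynaptic cell makes at most one contact with any given
#' postsynaptic cell; cells are wired independently of each other. The
#' realized per-presynaptic fan-out is then random with mean
#' `n_post * synapses_per_post / n_pre`. The map is frozen after
#' construction.
#'
#' With `method = "regular"` the per-presynaptic fan-out is made *exactly*
#' equal for all presynaptic cells (a random bipartite regular wiring,
#' requiring `n_post * synapses_per_post` divisible by `n_pre`), still with
#' at most one contact per pre-post pair. This variant is provided for
#' sensitivity checks against the emergent-fan-out default.
#'
#' @param spec A [pathway_spec()].
#' @param n_post Number of postsynaptic cells.
#' @param seed Optional integer seed.
#' @param method `"uniform"` (default, independent per-cell sampling) or
#'   `"regular"` (exact equal fan-out).
#' @return Object of class `projection_map`: fields `spec`, `n_post`,
#'   `pre` (integer matrix `n_post x synapses_per_post`; `pre[i, s]` is the
#'   1-based presynaptic cell wired to slot `s` of cell `i`), `seed`,
#'   `method`.
#' @export
build_projection <- function(spec, n_post, seed = NULL,
                             method = c("uniform", "regular")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "pathway_spec"), is_count(n_post, 1))
  n_post <- as.integer(n_post)
  s <- spec$synapses_per_post
  if (s > spec$n_pre) {
    stop(sprintf(
      "infeasible: %d synapse slots per cell but only %d presynaptic cells (at most one contact per pair)",
      s, spec$n_pre))
  }
  # edge-count consistency with the declared fan-out, 1 unit per post cell
  if (abs(spec$n_pre * as.numeric(spec$fanout) - n_post * as.numeric(s)) >
        n_post) {
    stop(sprintf(
      "inconsistent pathway: n_pre * fanout = %.0f but n_post * synapses_per_post = %.0f",
      spec$n_pre * as.numeric(spec$fanout), n_post * as.numeric(s)))
  }
  pre <- with_seed(seed, {
    if (method == "uniform") {
      t(vapply(seq_len(n_post), function(i) sample.int(spec$n_pre, s),
               integer(s)))
    } else {
      .regular_wiring(spec$n_pre, n_post, s)
    }
  })
  structure(
    list(spec = spec, n_post = n_post, pre = pre,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         method = method),
    class = "projection_map"
  )
}

# Random bipartite wiring with exact per-presynaptic fan-out and distinct
# presynaptic IDs within each postsynaptic cell. Deal a shuffled multiset of
# presynaptic IDs (each repeated fanout times) into rows, then repair
# within-row duplicates by swapping with other rows.
.regular_wiring <- function(n_pre, n_post, s) {
  total <- n_post * s
  if (total %% n_pre != 0) {
    stop("regular wiring needs n_post * synapses_per_post divisible by n_pre")
  }
  fan <- total %/% n_pre
  if (fan > n_post) stop("regular wiring infeasible: fanout exceeds n_post")
  pool <- sample(rep(seq_len(n_pre), fan))
  m <- matrix(pool, nrow = n_post, ncol = s)
  for (iter in 1:1000) {
    bad <- which(apply(m, 1, anyDuplicated) > 0)
    if (length(bad) == 0) break
    for (i in bad) {
      dup <- which(duplicated(m[i, ]))
      for (d in dup) {
        # swap the duplicate with a random entry elsewhere that keeps both
        # rows duplicate-free
        repeat {
          j <- sample.int(n_post, 1)
          cs <- sample.int(s, 1)
          if (j == i) next
          v <- m[j, cs]
          if (!(v %in% m[i, ]) && !(m[i, d] %in% m[j, -cs])) {
            m[j, cs] <- m[i, d]
            m[i, d] <- v
            break
          }
        }
      }
    }
  }
  if (any(apply(m, 1, anyDuplicated) > 0)) {
    stop("regular wiring failed to resolve duplicate contacts")
  }
  m
}

#' @export
print.projection_map <- function(x, ...) {
  cat(sprintf(
    "<projection_map> %s: %d pre -> %d post, %d slots/cell (%s wiring)\n",
    x$spec$name, x$spec$n_pre, x$n_post, x$spec$synapses_per_post, x$method))
  invisible(x)
}

#' Realized fan-out of a projection map
#'
#' @param map A [build_projection()] result.
#' @return Integer vector of length `n_pre`: number of postsynaptic targets
#'   per presynaptic cell.
#' @export
realized_fanout <- function(map) {
  stopifnot(inherits(map, "projection_map"))
  tabulate(as.vector(map$pre), nbins = map$spec$n_pre)
}

#' Active synapse slots per postsynaptic cell for a given input pattern
#'
#' Projects a presynaptic activity pattern through the map: for each
#' postsynaptic cell, returns the slot indices whose presynaptic cell is
#' active in the input.
#'
#' @param map A [build_projection()] result.
#' @param input A [binary_pattern()] of length `map$spec$n_pre`.
#' @return List of length `n_post`; element `i` is the integer vector of
#'   active slot indices (in `1:synapses_per_post`) of cell `i`.
#' @export
active_synapses <- function(map, input) {
  stopifnot(inherits(map, "projection_map"), is_binary_pattern(input))
  if (input$length != map$spec$n_pre) {
    stop(sprintf("input length %d does not match n_pre %d",
                 input$length, map$spec$n_pre))
  }
  z <- logical(map$spec$n_pre)
  z[input$active] <- TRUE
  act <- matrix(z[map$pre], nrow = map$n_post)
  lapply(seq_len(map$n_post), function(i) which(act[i, ]))
}

# Fast path used by the surrogate: logical activity matrix n_post x s.
.active_matrix <- function(map, input) {
  z <- logical(map$spec$n_pre)
  z[input$active] <- TRUE
  matrix(z[map$pre], nrow = map$n_post)
}

# ---- connectivity file format ------------------------------------------

#' Read and write projection maps
#'
#' The on-disk format is a headered TSV edge list with columns `post_id`,
#' `slot`, `pre_id` (all **0-based**), one row per synapse, in
#' (postsynaptic cell, slot) order, plus a JSON sidecar (`<path>.json`)
#' recording the pathway spec, `n_post`, `seed` and wiring method. A
#' write/read round trip is lossless and order-preserving.
#'
#' @param map A `projection_map`.
#' @param path TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_projection()` returns `path` invisibly; `read_projection()`
#'   returns a `projection_map`.
#' @export
write_projection <- function(map, path) {
  stopifnot(inherits(map, "projection_map"))
  s <- map$spec$synapses_per_post
  df <- data.frame(
    post_id = rep(seq_len(map$n_post), each = s) - 1L,
    slot = rep(seq_len(s), times = map$n_post) - 1L,
    pre_id = as.vector(t(map$pre)) - 1L
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(
    name = map$spec$name,
    n_pre = map$spec$n_pre,
    synapses_per_post = s,
    fanout = map$spec$fanout,
    n_post = map$n_post,
    seed = map$seed,
    method = map$method,
    index_base = 0
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  spec <- pathway_spec(side$name, side$n_pre, side$synapses_per_post,
                       side$fanout)
  s <- spec$synapses_per_post
  ord <- order(df$post_id, df$slot)
  pre <- matrix(df$pre_id[ord] + 1L, nrow = side$n_post, ncol = s,
                byrow = TRUE)
  structure(
    list(spec = spec, n_post = as.integer(side$n_post), pre = pre,
         seed = if (is.null(side$seed) || is.na(side$seed)) NA_integer_
                else as.integer(side$seed),
         method = side$method),
    class = "projection_map"
  )
}
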