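#' Forward-simulate a dispersal-extinction-cladogenesis history on a tree
#'
#' Simulates range evolution from a known root range down a dated tree:
#' along branches, per-area gains (rate `d` times the number of occupied
#' source areas, under an all-ones dispersal multiplier matrix by default)
#' and per-area losses (rate `e`) compete as exponentials; at every internal
#' node a cladogenetic event is drawn from the DEC event set (vicariance,
#' subset sympatry, sympatric copying; founder-event jumps with total weight
#' `j` when `j > 0`). Lineages whose range goes extinct (empty) terminate
#' the replicate, which is resampled by default.
#'
#' @param tree a dated bifurcating `phylo` tree (branch lengths in Myr).
#' @param d,e,j anagenetic dispersal and extinction rates (events/Myr per
#'   area) and cladogenetic jump weight in `[0, 1)`.
#' @param areas character vector of single-letter area names.
#' @param root_range root range, e.g. `"B"` or `"AB"` (subset of `areas`).
#' @param max_range_size maximum number of areas a range may span.
#' @param dispersal_matrix optional areas x areas multiplier matrix
#'   (all-ones default: no distance scaling).
#' @param seed integer seed.
#' @param resample if `TRUE` (default) a replicate in which any lineage's
#'   range goes extinct is discarded and redrawn, up to `max_attempts`
#'   times; if `FALSE` the history is returned with `extinct = TRUE`.
#' @param max_attempts resampling cap; exceeding it is an error.
#'
#' @return An object of class `simulated_history`: `tree`, `areas`,
#'   `params` (d, e, j), `tip_ranges` (named character vector), `events`
#'   (data frame: `node` — child node of the edge the event sits on, `time`
#'   — absolute time from the root, `type` — dispersal / extinction /
#'   sympatry / subset / vicariance / jump, `from`, `to` — range strings,
#'   `area` — gained/lost/jumped-to area for anagenetic and jump events),
#'   `extinct` flag, and `attempts` used.
#' @seealso [replay_history()] to rebuild tip ranges from the event log.
#' @export
simulate_dec <- function(tree, d, e, j = 0, areas, root_range,
                         max_range_size = length(areas),
                         dispersal_matrix = NULL, seed = 1L,
                         resample = TRUE, max_attempts = 100L) {
  check_tree(tree)
  if (d < 0 || e < 0 || j < 0 || j >= 1)
    stop("rates must satisfy d,e >= 0 and 0 <= j < 1", call. = FALSE)
  nA <- length(areas)
  states <- dec_states(nA, max_range_size)
  root_mask <- areas_to_mask(root_range, areas)
  if (root_mask == 0L) stop("'root_range' must be non-empty", call. = FALSE)
  state_of(root_mask, states)   # validates against max_range_size
  m <- dispersal_matrix
  if (is.null(m)) m <- matrix(1, nA, nA)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  for (attempt in seq_len(max_attempts)) {
    h <- sim_dec_once(tree, d, e, j, areas, root_mask, max_range_size, m)
    if (!h$extinct || !resample) {
      h$attempts <- attempt
      h$tree <- tree; h$areas <- areas
      h$params <- c(d = d, e = e, j = j)
      h$seed <- seed
      class(h) <- "simulated_history"
      return(h)
    }
  }
  stop("range extinction in every replicate after ", max_attempts,
       " attempts; lower 'e' or set resample = FALSE", call. = FALSE)
}

sim_dec_once <- function(tree, d, e, j, areas, root_mask, max_size, m) {
  tree <- stats::reorder(tree, "cladewise")   # preorder edge traversal
  nA <- length(areas)
  bits <- bitwShiftL(1L, seq_len(nA) - 1L)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n_nodes <- ntip + tree$Nnode
  heights <- ape::node.depth.edgelength(tree)

  ev <- list(node = integer(0), time = numeric(0), type = character(0),
             from = character(0), to = character(0), area = character(0))
  log_event <- function(node, time, type, from, to, area = NA_character_) {
    ev$node <<- c(ev$node, node); ev$time <<- c(ev$time, time)
    ev$type <<- c(ev$type, type)
    ev$from <<- c(ev$from, mask_to_string(from, areas))
    ev$to <<- c(ev$to, mask_to_string(to, areas))
    ev$area <<- c(ev$area, area)
  }

  start_state <- rep(NA_integer_, n_nodes)   # range mask at top of the edge
  end_state <- rep(NA_integer_, n_nodes)     # range mask at the node
  extinct <- FALSE

  split_at <- function(node, mask) {
    tab <- clado_events(mask, nA, NULL, j)
    k <- sample.int(length(tab$prob), 1L, prob = tab$prob)
    children <- tree$edge[tree$edge[, 1] == node, 2]
    start_state[children[1]] <<- tab$left[k]
    start_state[children[2]] <<- tab$right[k]
    for (ch in children) {
      to <- start_state[ch]
      area <- if (tab$type[k] == "jump") {
        new <- setdiff(c(mask_areas(tab$left[k], areas),
                         mask_areas(tab$right[k], areas)),
                       mask_areas(mask, areas))
        if (length(new)) new[1] else NA_character_
      } else NA_character_
      log_event(ch, heights[node], tab$type[k], mask, to, area)
    }
  }

  end_state[root] <- root_mask
  split_at(root, root_mask)
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    mask <- start_state[child]
    t0 <- heights[parent]; t1 <- heights[child]
    t <- t0
    repeat {
      inR <- which(bitwAnd(mask, bits) > 0L)
      outR <- which(bitwAnd(mask, bits) == 0L)
      if (length(inR) >= max_size) outR <- integer(0)
      gain_rates <- if (length(outR)) d * colSums(m[inR, outR, drop = FALSE])
                    else numeric(0)
      loss_rates <- rep(e, length(inR))
      total <- sum(gain_rates) + sum(loss_rates)
      if (total <= 0) break
      t <- t + stats::rexp(1, total)
      if (t >= t1) break
      pick <- sample.int(length(gain_rates) + length(loss_rates), 1L,
                         prob = c(gain_rates, loss_rates))
      if (pick <= length(gain_rates)) {
        k <- outR[pick]
        new_mask <- mask + bits[k]
        log_event(child, t, "dispersal", mask, new_mask, areas[k])
      } else {
        k <- inR[pick - length(gain_rates)]
        new_mask <- mask - bits[k]
        log_event(child, t, "extinction", mask, new_mask, areas[k])
      }
      mask <- new_mask
      if (mask == 0L) { extinct <- TRUE; break }
    }
    end_state[child] <- mask
    if (extinct) break
    if (child > ntip) split_at(child, mask)
  }

  events <- data.frame(node = ev$node, time = ev$time, type = ev$type,
                       from = ev$from, to = ev$to, area = ev$area,
                       stringsAsFactors = FALSE)
  events <- events[order(events$time, events$node), , drop = FALSE]
  rownames(events) <- NULL
  tips <- mask_to_string(end_state[seq_len(ntip)], areas)
  names(tips) <- tree$tip.label
  list(tip_ranges = tips, events = events, extinct = extinct,
       root_range = mask_to_string(root_mask, areas))
}

#' Replay a simulated history's event log
#'
#' Reconstructs every tip range by replaying the logged cladogenetic and
#' anagenetic events from the root state; used to verify that the event log
#' fully determines the realized history.
#'
#' @param history a `simulated_history`.
#' @return Named character vector of tip ranges.
#' @export
replay_history <- function(history) {
  stopifnot(inherits(history, "simulated_history"))
  tree <- history$tree; ev <- history$events
  ntip <- length(tree$tip.label)
  state <- rep(NA_character_, ntip + tree$Nnode)
  clado <- ev$type %in% c("sympatry", "subset", "vicariance", "jump")
  for (i in which(clado)) state[ev$node[i]] <- ev$to[i]
  ana <- ev[!clado, , drop = FALSE]
  ana <- ana[order(ana$time), , drop = FALSE]
  for (i in seq_len(nrow(ana))) state[ana$node[i]] <- ana$to[i]
  tips <- state[seq_len(ntip)]
  names(tips) <- tree$tip.label
  tips
}

#' @export
print.simulated_history <- function(x, ...) {
  cat("<simulated_history> ", length(x$tip_ranges), " tips, areas ",
      paste(x$areas, collapse = ""), "; d=", x$params["d"], " e=",
      x$params["e"], " j=", x$params["j"], "; ", nrow(x$events),
      " events", if (x$extinct) " [EXTINCT]", "\n", sep = "")
  invisible(x)
}

#' Write a simulated history to disk
#'
#' Writes the tree as newick and the event log, tip ranges, and parameters
#' as JSON.
#'
#' @param history a `simulated_history`.
#' @param tree_file,json_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_history <- function(history, tree_file, json_file) {
  stopifnot(inherits(history, "simulated_history"))
  ape::write.tree(history$tree, tree_file)
  jsonlite::write_json(
    list(areas = history$areas, params = as.list(history$params),
         root_range = history$root_range,
         tip_ranges = as.list(history$tip_ranges),
         events = history$events),
    json_file, auto_unbox = TRUE, digits = NA)
  invisible(c(tree_file, json_file))
}
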