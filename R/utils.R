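## Convert a table of lineage records from a forward-time simulation into the
## reconstructed (surviving-terminals-only) ultrametric phylo object.
##
## `lin` is a data frame with columns:
##   id      integer, 1..k in birth order
##   parent  id of the parent lineage (0 for a starting lineage)
##   t_birth forward time of origin (0 = start of simulation)
##   t_end   forward time the lineage stopped (speciation or extinction), or
##           `present` if it reached the present
##   alive   TRUE if the lineage is a surviving terminal
##   label   tip label for surviving terminals
## Speciation is modelled as the parent ending at t_end and two children being
## born there. Returns NULL if fewer than 2 terminals survive.
lineages_to_phylo <- function(lin, present) {
  k <- nrow(lin)
  children <- vector("list", k)
  for (i in seq_len(k)) {
    p <- lin$parent[i]
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  ## surviving-descendant flag, processed in reverse birth order
  surv <- lin$alive
  for (i in rev(seq_len(k))) {
    p <- lin$parent[i]
    if (p > 0 && surv[i]) surv[p] <- TRUE
  }
  roots <- which(lin$parent == 0 & surv)
  n_tips <- sum(lin$alive)
  if (n_tips < 2) return(NULL)

  surv_children <- lapply(seq_len(k), function(i) {
    cc <- children[[i]]
    cc[surv[cc]]
  })
  ## chase pass-through chains: from lineage i, follow single surviving
  ## children until a terminal or a bifurcation
  chase <- function(i) {
    while (TRUE) {
      cc <- surv_children[[i]]
      if (lin$alive[i] || length(cc) == 2L) return(i)
      if (length(cc) == 0L) stop("internal error: dead-end surviving lineage")
      i <- cc[1]
    }
  }

  edges <- matrix(0L, nrow = 2 * n_tips - 2, ncol = 2)
  elen <- numeric(2 * n_tips - 2)
  labels <- character(n_tips)
  n_node_total <- n_tips - 1L
  tip_ctr <- 0L; node_ctr <- 0L; edge_ctr <- 0L
  new_node <- function() { node_ctr <<- node_ctr + 1L; n_tips + node_ctr }

  ## stack items: (lineage at start of an edge, parent node id, start time)
  if (length(roots) == 2L) {
    root_id <- n_tips + 1L; node_ctr <- 1L
    stack <- list(list(lin = roots[1], pnode = root_id, t0 = 0),
                  list(lin = roots[2], pnode = root_id, t0 = 0))
  } else {
    top <- chase(roots[1])
    if (lin$alive[top] && length(surv_children[[top]]) < 2L) return(NULL)
    root_id <- n_tips + 1L; node_ctr <- 1L
    cc <- surv_children[[top]]
    stack <- list(list(lin = cc[1], pnode = root_id, t0 = lin$t_end[top]),
                  list(lin = cc[2], pnode = root_id, t0 = lin$t_end[top]))
  }
  while (length(stack)) {
    it <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- chase(it$lin)
    if (lin$alive[i]) {
      tip_ctr <- tip_ctr + 1L
      edge_ctr <- edge_ctr + 1L
      edges[edge_ctr, ] <- c(it$pnode, tip_ctr)
      elen[edge_ctr] <- present - it$t0
      labels[tip_ctr] <- lin$label[i]
    } else {
      v <- new_node()
      edge_ctr <- edge_ctr + 1L
      edges[edge_ctr, ] <- c(it$pnode, v)
      elen[edge_ctr] <- lin$t_end[i] - it$t0
      cc <- surv_children[[i]]
      stack[[length(stack) + 1L]] <- list(lin = cc[1], pnode = v, t0 = lin$t_end[i])
      stack[[length(stack) + 1L]] <- list(lin = cc[2], pnode = v, t0 = lin$t_end[i])
    }
  }
  tr <- structure(list(edge = edges, edge.length = elen, tip.label = labels,
                       Nnode = n_node_total), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Deterministic child seed for a named stage
#'
#' Derives a stage-specific integer seed (< 2^31) from one global seed, so
#' that a single \code{--seed} reproducibly drives every stochastic stage
#' of an analysis while keeping the stages' random streams distinct.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
spawn_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

write_tsv <- function(df, path, digits = 12) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
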