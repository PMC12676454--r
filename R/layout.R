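#' Deterministic layered layout for a process diagram
#'
#' Places nodes left-to-right by longest-path rank over the arc flow
#' (consumption: complex to process; production: process to complex).
#' Arcs that would close a cycle — e.g. the self-loop of a modification
#' rule through its complex — are ignored for ranking, in deterministic
#' arc order. Within a rank, complexes come before processes, each in
#' their deterministic node order, stacked vertically. Boxes never
#' overlap: every node owns a distinct (rank, slot) cell and the gutters
#' exceed zero.
#'
#' @param graph an `mpd_graph`.
#' @param box_w,box_h node box size in abstract pixel units.
#' @param gutter spacing between boxes.
#' @return a data.frame with columns `id`, `kind` ("complex"/"process"),
#'   `ref` (composition key or rule id), `x`, `y`, `w`, `h`, `rank`.
#' @export
mpd_layout <- function(graph, box_w = 80, box_h = 40, gutter = 40) {
  ckeys <- names(graph$complex_nodes)
  if (is.null(ckeys)) ckeys <- character(0)
  pids <- vapply(graph$process_nodes, `[[`, "", "rule_id")
  ids <- c(paste0("c:", ckeys, recycle0 = TRUE),
           paste0("p:", pids, recycle0 = TRUE))
  n <- length(ids)
  if (!n)
    return(data.frame(id = character(0), kind = character(0),
                      ref = character(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  idx <- stats::setNames(seq_len(n), ids)

  # greedy acyclic edge set in arc order
  adj <- lapply(seq_len(n), function(i) integer(0))
  reaches <- function(from, to) {
    stack <- from
    seen <- rep(FALSE, n)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]])
    }
    FALSE
  }
  edges <- list()
  for (a in graph$arcs) {
    ep <- if (a$kind == "CONSUMPTION")
      c(paste0("c:", a$complex_key), paste0("p:", a$rule_id))
    else c(paste0("p:", a$rule_id), paste0("c:", a$complex_key))
    u <- idx[[ep[1]]]
    v <- idx[[ep[2]]]
    if (!reaches(v, u)) {
      adj[[u]] <- c(adj[[u]], v)
      edges[[length(edges) + 1]] <- c(u, v)
    }
  }

  # longest-path ranks on the kept DAG
  rank <- rep(0L, n)
  indeg <- rep(0L, n)
  for (e in edges) indeg[e[2]] <- indeg[e[2]] + 1L
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      rank[w] <- max(rank[w], rank[v] + 1L)
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }

  kind <- rep(c("complex", "process"), c(length(ckeys), length(pids)))
  ref <- c(ckeys, pids)
  # vertical slot within rank: complexes first, then processes, each in
  # their deterministic order (sorted keys / rule ordinals)
  slot <- integer(n)
  for (rk in sort(unique(rank))) {
    members <- which(rank == rk)
    members <- members[order(kind[members] != "complex", members)]
    slot[members] <- seq_along(members) - 1L
  }
  data.frame(id = ids, kind = kind, ref = ref,
             x = rank * (box_w + gutter),
             y = slot * (box_h + gutter),
             w = box_w, h = box_h, rank = rank,
             stringsAsFactors = FALSE)
}
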