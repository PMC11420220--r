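# Lineage reconstruction from shared copy-number aberrations.

# Cluster calls into distinct aberration events. Whole-chromosome calls of
# the same (chrom, direction) are one event; segmental calls of the same
# (chrom, direction) are merged greedily when their reciprocal overlap is
# >= overlap.
aberration_events <- function(calls, overlap = 0.5) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(cell_id = character(), event = character()))
  }
  whole <- calls |>
    dplyr::filter(.data$scope == "whole") |>
    dplyr::mutate(event = paste0(.data$chrom, ":", .data$direction, ":whole"))
  seg <- dplyr::filter(calls, .data$scope == "segmental")
  if (nrow(seg) > 0) {
    seg <- seg |>
      dplyr::group_by(.data$chrom, .data$direction) |>
      dplyr::group_modify(function(df, key) {
        df <- dplyr::arrange(df, .data$start)
        grp <- integer(nrow(df))
        reps <- list()
        for (i in seq_len(nrow(df))) {
          hit <- 0L
          for (g in seq_along(reps)) {
            if (reciprocal_overlap(df$start[i], df$end[i],
                                   reps[[g]][1], reps[[g]][2]) >= overlap) {
              hit <- g
              break
            }
          }
          if (hit == 0L) {
            reps[[length(reps) + 1L]] <- c(df$start[i], df$end[i])
            hit <- length(reps)
          }
          grp[i] <- hit
        }
        df$event <- sprintf("%s:%s:seg%02d", key$chrom, key$direction, grp)
        df
      }) |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(whole, seg) |>
    dplyr::distinct(.data$cell_id, .data$event)
}

#' Reconstruct the cell lineage of one embryo from shared aberrations
#'
#' Cells are grouped into clades by identical aberration-event sets (event =
#' a whole-chromosome gain/loss, or a cluster of overlapping segmental
#' calls). Clades are nested by the subset relation on their event sets --
#' a daughter lineage inherits its ancestor's aberrations and may add new
#' ones -- with the euploid zygote as root. Clades whose sets overlap
#' without nesting are left as siblings and flagged ambiguous. Clades that
#' differ only by a complementary gain/loss of the same region are joined
#' under a common virtual ancestor (the nondisjunction division).
#'
#' The division stage of an event is estimated from clade sizes as
#' `2 ^ round(log2(n_total / n_carrying))`, expressed as a cell stage;
#' `n_carrying` counts every cell whose set contains the event and
#' `n_total` all QC-passed cells of the embryo.
#'
#' @param calls Mitotic calls of one embryo.
#' @param cell_ids All QC-passed cell ids.
#' @param embryo_id Label.
#' @param overlap Reciprocal-overlap threshold for event clustering.
#' @return A `lineage_tree`: list with `embryo_id`, `nodes` (tibble:
#'   `node_id`, `parent_id`, `label`, `events` list-column, `n_cells`,
#'   `cell_ids` list-column, `ambiguous`) and `events` (tibble: `event`,
#'   `n_carrying`, `stage_cells`).
#' @export
reconstruct_lineage <- function(calls, cell_ids, embryo_id = "embryo",
                                overlap = 0.5) {
  ev <- aberration_events(calls, overlap)
  n_total <- length(cell_ids)
  abort_if(n_total == 0, "zero cells")
  sets <- lapply(cell_ids, function(cid) sort(ev$event[ev$cell_id == cid]))
  keys <- vapply(sets, paste, character(1), collapse = "|")
  uniq <- !duplicated(keys)
  clade_keys <- keys[uniq]
  clade_sets <- sets[uniq]
  # ensure a root clade exists even if no cell is euploid
  if (!"" %in% clade_keys) {
    clade_keys <- c("", clade_keys)
    clade_sets <- c(list(character(0)), clade_sets)
  }
  ord <- order(vapply(clade_sets, length, integer(1)))
  clade_keys <- clade_keys[ord]
  clade_sets <- clade_sets[ord]
  m <- length(clade_sets)
  parent <- rep(NA_integer_, m)
  ambiguous <- rep(FALSE, m)
  for (i in seq_len(m)) {
    si <- clade_sets[[i]]
    if (length(si) == 0) next # root keeps parent NA
    best <- 1L # root (empty set) is always a valid ancestor
    for (j in seq_len(m)) {
      sj <- clade_sets[[j]]
      if (j == i) next
      if (length(sj) < length(si) && all(sj %in% si)) {
        if (length(sj) > length(clade_sets[[best]])) best <- j
      } else if (length(intersect(sj, si)) > 0 &&
                 !all(sj %in% si) && !all(si %in% sj)) {
        # overlapping but not nested: leave as siblings, flag it
        ambiguous[i] <- TRUE
      }
    }
    parent[i] <- best
  }
  members <- lapply(clade_keys, function(k) cell_ids[keys == k])
  nodes <- tibble::tibble(
    node_id = seq_len(m),
    parent_id = parent,
    label = ifelse(clade_keys == "", "euploid", clade_keys),
    events = clade_sets,
    n_cells = lengths(members),
    cell_ids = members,
    ambiguous = ambiguous
  )
  # virtual ancestors for complementary sibling clades
  nodes <- join_complementary_clades(nodes)
  ev_tbl <- if (nrow(ev) == 0) {
    tibble::tibble(event = character(), n_carrying = integer(),
                   stage_cells = numeric())
  } else {
    ev |>
      dplyr::count(.data$event, name = "n_carrying") |>
      dplyr::mutate(stage_cells = 2^round(log2(n_total / .data$n_carrying)))
  }
  structure(list(embryo_id = embryo_id, n_total = n_total,
                 nodes = nodes, events = ev_tbl),
            class = "lineage_tree")
}

# "chr4:gain:whole" <-> "chr4:loss:whole" etc.
complement_event <- function(e) {
  swap <- function(x) ifelse(grepl(":gain:", x),
                             sub(":gain:", ":loss:", x),
                             sub(":loss:", ":gain:", x))
  swap(e)
}

join_complementary_clades <- function(nodes) {
  n0 <- nrow(nodes)
  next_id <- max(nodes$node_id) + 1L
  for (i in seq_len(n0)) {
    for (j in seq_len(n0)) {
      if (j <= i) next
      si <- nodes$events[[i]]; sj <- nodes$events[[j]]
      if (length(si) == 0 || length(sj) == 0) next
      if (nodes$parent_id[i] != nodes$parent_id[j] ||
          is.na(nodes$parent_id[i])) next
      # differ by exactly one complementary event on top of a shared core
      di <- setdiff(si, sj); dj <- setdiff(sj, si)
      if (length(di) == 1 && length(dj) == 1 &&
          complement_event(di) == dj) {
        nodes <- dplyr::add_row(nodes,
          node_id = next_id, parent_id = nodes$parent_id[i],
          label = paste0("nondisjunction:", sub(":(gain|loss):", ":", di)),
          events = list(intersect(si, sj)),
          n_cells = 0L, cell_ids = list(character(0)), ambiguous = FALSE)
        nodes$parent_id[c(i, j)] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  nodes
}

#' Export a lineage tree as a Newick string
#'
#' Clades become internal labels; each clade's member cells are attached as
#' leaves. Parses cleanly with `ape::read.tree`.
#' @param tree A `lineage_tree`.
#' @return Newick string (terminated by `;`).
#' @export
lineage_newick <- function(tree) {
  nodes <- tree$nodes
  build <- function(id) {
    kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
    leaves <- nodes$cell_ids[[which(nodes$node_id == id)]]
    parts <- c(leaves, vapply(kids, build, character(1)))
    lab <- gsub("[ ():,;]", "_", nodes$label[nodes$node_id == id])
    if (length(parts) == 0) return(lab)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  root <- nodes$node_id[is.na(nodes$parent_id)][1]
  paste0(build(root), ";")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("Lineage tree for", x$embryo_id, "-", x$n_total, "cells,",
      nrow(x$nodes), "clades\n")
  print(dplyr::select(x$nodes, "node_id", "parent_id", "label", "n_cells",
                      "ambiguous"))
  if (nrow(x$events) > 0) {
    cat("events:\n")
    print(x$events)
  }
  invisible(x)
}
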