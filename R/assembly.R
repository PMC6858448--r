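# best ungapped overlap between x and y (y on either strand), anchored on
# shared word_size-mers; identity is computed over the overlap region
.best_overlap <- function(x_chars, y_chars, word_size = 8L,
                          min_overlap = word_size) {
  best <- list(identity = 0, offset = NA_integer_, strand = NA_character_)
  x_str <- paste(x_chars, collapse = "")
  lx <- length(x_chars)
  kx <- substring(x_str, seq_len(max(lx - word_size + 1L, 0L)),
                  seq_len(max(lx - word_size + 1L, 0L)) + word_size - 1L)
  for (strand in c("+", "-")) {
    yc <- if (strand == "+") y_chars else {
      strsplit(revcomp(paste(y_chars, collapse = "")), "",
               fixed = TRUE)[[1]]
    }
    ly <- length(yc)
    y_str <- paste(yc, collapse = "")
    ky <- substring(y_str, seq_len(max(ly - word_size + 1L, 0L)),
                    seq_len(max(ly - word_size + 1L, 0L)) + word_size - 1L)
    shared <- intersect(kx, ky)
    if (!length(shared)) next
    offs <- unique(unlist(lapply(shared, function(k) {
      outer(which(kx == k), which(ky == k), `-`)
    })))
    for (d in offs) {
      s <- max(1L, d + 1L)
      e <- min(lx, d + ly)
      if (e - s + 1L < min_overlap) next
      ident <- sum(x_chars[s:e] == yc[(s - d):(e - d)]) / (e - s + 1L)
      if (ident > best$identity ||
          (ident == best$identity && is.na(best$offset))) {
        best <- list(identity = ident, offset = d, strand = strand)
      }
    }
  }
  best
}

#' All-vs-all spacer matching graph
#'
#' Connects two spacers when the best ungapped extension from a shared
#' `word_size`-mer (either strand) reaches an identity above
#' `min_identity` over the overlapping region. Spacers sampled from the
#' same genome tile it with partial overlaps, so identity is computed
#' over the overlap, not the full spacer length.
#'
#' @param spacers Named character vector of spacer (centroid) sequences.
#' @param min_identity Overlap identity threshold, strict (default 0.7).
#' @param word_size Seed length (default 8).
#' @param min_overlap Minimum overlap length considered (default
#'   `word_size`).
#' @return Object of class `spacer_match_graph`: `nodes` and undirected
#'   `edges` (`a`, `b`, `identity`, `strand`, `offset`).
#' @export
all_vs_all_matches <- function(spacers, min_identity = 0.7,
                               word_size = 8L, min_overlap = word_size) {
  if (length(spacers) < 2) stop("need at least 2 spacers")
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer%04d", seq_along(spacers))
  }
  chars <- lapply(spacers, function(s) {
    strsplit(toupper(s), "", fixed = TRUE)[[1]]
  })
  n <- length(spacers)
  # prescreen: only pairs sharing a word_size-mer (either strand) can
  # have a seeded overlap
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < word_size) return(character(0))
    unique(substring(s, seq_len(L - word_size + 1L),
                     seq_len(L - word_size + 1L) + word_size - 1L))
  }
  fwd <- vapply(spacers, function(s) paste(toupper(s), collapse = ""),
                character(1))
  fwd_k <- lapply(fwd, kmers_of)
  rc_k <- lapply(revcomp(fwd), kmers_of)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (k in fwd_k[[i]]) assign(k, c(index[[k]], i), envir = index)
  }
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- unique(unlist(lapply(c(fwd_k[[i]], rc_k[[i]]),
                                 function(k) index[[k]])))
    cand[[i]] <- hits[hits > i]
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (j in cand[[i]]) {
      b <- .best_overlap(chars[[i]], chars[[j]], word_size, min_overlap)
      if (!is.na(b$offset) && b$identity > min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = names(spacers)[i], b = names(spacers)[j],
          identity = b$identity, strand = b$strand, offset = b$offset
        )
      }
    }
  }
  edges <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(a = character(0), b = character(0), identity = numeric(0),
               strand = character(0), offset = integer(0))
  }
  structure(list(nodes = names(spacers), edges = edges,
                 sequences = stats::setNames(toupper(unname(spacers)),
                                             names(spacers))),
            class = "spacer_match_graph")
}

#' @export
print.spacer_match_graph <- function(x, ...) {
  cat("Spacer match graph:", length(x$nodes), "spacers,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Tile spacers from each match-graph component into contigs
#'
#' Per connected component, a greedy best-overlap layout: starting from
#' the highest-degree spacer, members are placed by descending edge
#' identity, each at the offset and orientation of its best overlap with
#' the already-laid-out consensus neighbourhood. Edges whose implied
#' offset disagrees with the layout by more than `offset_tolerance` are
#' dropped (logged) and the component re-decomposed, replacing the manual
#' alignment curation step of the original procedure. The consensus is
#' the per-column majority base (ties: lexicographically smallest);
#' single spacers are emitted as-is.
#'
#' @param graph An [all_vs_all_matches()] result.
#' @param word_size Seed length for layout-time overlap checks.
#' @param offset_tolerance Allowed disagreement (nt) between an edge's
#'   implied offset and the layout.
#' @return Object of class `tiled_contigs`: list `contigs` of records
#'   (`contig_id`, `consensus`, `layout` with `spacer_id`, `offset`,
#'   `strand`, `component_id`, `depth`), and `dropped_edges` log.
#' @export
tile_contigs <- function(graph, word_size = 8L, offset_tolerance = 2L) {
  stopifnot(inherits(graph, "spacer_match_graph"))
  seqs <- graph$sequences
  edges <- graph$edges
  dropped <- edges[0, , drop = FALSE]

  repeat {
    ig <- igraph::graph_from_data_frame(
      edges[, c("a", "b")], directed = FALSE,
      vertices = data.frame(name = graph$nodes)
    )
    membership <- igraph::components(ig)$membership
    conflict <- NULL
    layouts <- list()

    for (comp in sort(unique(membership))) {
      members <- names(membership)[membership == comp]
      if (length(members) == 1L) {
        layouts[[length(layouts) + 1L]] <- list(
          component_id = comp,
          layout = data.frame(spacer_id = members, offset = 0L,
                              strand = "+")
        )
        next
      }
      ce <- edges[edges$a %in% members & edges$b %in% members, ,
                  drop = FALSE]
      deg <- table(c(ce$a, ce$b))
      root <- names(deg)[order(-as.integer(deg), names(deg))][1L]
      placed <- stats::setNames(list(list(offset = 0L, strand = "+")),
                                root)
      ord <- order(-ce$identity, ce$a, ce$b)
      remaining <- ord
      progress <- TRUE
      while (length(remaining) && progress && is.null(conflict)) {
        progress <- FALSE
        for (pos in seq_along(remaining)) {
          ei <- remaining[pos]
          a <- ce$a[ei]; b <- ce$b[ei]
          ina <- a %in% names(placed); inb <- b %in% names(placed)
          if (ina == inb) {
            if (ina && inb) {
              # consistency check for an edge within the placed set
              pa <- placed[[a]]; pb <- placed[[b]]
              oa <- .oriented(seqs[[a]], pa$strand)
              ob_exp <- pb$offset - pa$offset
              bo <- .best_overlap(strsplit(oa, "", fixed = TRUE)[[1]],
                                  strsplit(seqs[[b]], "",
                                           fixed = TRUE)[[1]],
                                  word_size)
              if (is.na(bo$offset) ||
                  abs(bo$offset - ob_exp) > offset_tolerance) {
                conflict <- ei
                break
              }
              remaining <- remaining[-pos]
              progress <- TRUE
              break
            }
            next
          }
          anchor <- if (ina) a else b
          new <- if (ina) b else a
          pa <- placed[[anchor]]
          oa <- .oriented(seqs[[anchor]], pa$strand)
          bo <- .best_overlap(strsplit(oa, "", fixed = TRUE)[[1]],
                              strsplit(seqs[[new]], "", fixed = TRUE)[[1]],
                              word_size)
          if (is.na(bo$offset)) {
            conflict <- ei
            break
          }
          placed[[new]] <- list(offset = pa$offset + bo$offset,
                                strand = bo$strand)
          remaining <- remaining[-pos]
          progress <- TRUE
          break
        }
      }
      if (!is.null(conflict)) break
      layouts[[length(layouts) + 1L]] <- list(
        component_id = comp,
        layout = data.frame(
          spacer_id = names(placed),
          offset = vapply(placed, `[[`, integer(1), "offset"),
          strand = vapply(placed, `[[`, character(1), "strand")
        )
      )
    }
    if (is.null(conflict)) break
    # split at the conflicting (weakest inconsistent) edge and retry
    key_all <- paste(edges$a, edges$b)
    bad <- edges[edges$a == ce$a[conflict] & edges$b == ce$b[conflict], ,
                 drop = FALSE]
    dropped <- rbind(dropped, bad)
    edges <- edges[!(edges$a == ce$a[conflict] &
                       edges$b == ce$b[conflict]), , drop = FALSE]
  }

  contigs <- lapply(seq_along(layouts), function(li) {
    lay <- layouts[[li]]$layout
    lay$offset <- lay$offset - min(lay$offset)
    width <- max(lay$offset + nchar(seqs[lay$spacer_id]))
    counts <- matrix(0L, nrow = 4, ncol = width,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (r in seq_len(nrow(lay))) {
      s <- .oriented(seqs[[lay$spacer_id[r]]], lay$strand[r])
      sc <- strsplit(s, "", fixed = TRUE)[[1]]
      cols <- lay$offset[r] + seq_along(sc)
      for (k in seq_along(sc)) {
        counts[sc[k], cols[k]] <- counts[sc[k], cols[k]] + 1L
      }
    }
    consensus <- paste(rownames(counts)[apply(counts, 2, which.max)],
                       collapse = "")
    list(contig_id = sprintf("contig%03d", li),
         consensus = consensus,
         layout = lay,
         component_id = layouts[[li]]$component_id,
         depth = colSums(counts))
  })
  structure(list(contigs = contigs, dropped_edges = dropped),
            class = "tiled_contigs")
}

.oriented <- function(s, strand) if (strand == "+") s else revcomp(s)

#' @export
print.tiled_contigs <- function(x, ...) {
  cat("Tiled contigs:", length(x$contigs), "\n")
  for (ct in x$contigs) {
    cat(sprintf("  %s: %d nt from %d spacers\n", ct$contig_id,
                nchar(ct$consensus), nrow(ct$layout)))
  }
  if (nrow(x$dropped_edges)) {
    cat("  dropped inconsistent edges:", nrow(x$dropped_edges), "\n")
  }
  invisible(x)
}
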