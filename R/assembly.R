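# A-Bruijn assembly: glue matched PRM peaks across aligned spectra into
# vertices, read contigs as heaviest consensus paths, and emit
# meta-contig consensus spectra.

#' Glue one network component into A-Bruijn vertices
#'
#' Coordinate frames are propagated from an anchor spectrum (the node
#' with the highest total peak score) along a maximum-score spanning
#' tree of the component's edges; an edge (a, b, shift) places a peak of
#' b at `mass + shift` in a's frame, so `offset_b = offset_a + shift`.
#' Non-tree edges whose shift disagrees with the propagated frames by
#' more than `frame_tol` are dropped (inconsistent cycles, logged via a
#' message). Matched peak pairs of the kept edges are merged by
#' union-find; a union that would put two peaks of one spectrum into one
#' vertex is refused and the offending pair dropped. Vertices whose
#' member frame masses spread over more than `frame_tol` are split by
#' single-linkage clustering. Unmatched peaks remain as singleton
#' vertices (they may carry true ladder masses). The frame is finally
#' translated so that the leftmost member spectrum starts at 0.
#'
#' @param prms Named list of `PRMSpectrum` (all nodes of the component).
#' @param alignments List of `PairwiseAlignment` within the component.
#' @param frame_tol Frame consistency tolerance (Da), default 0.35.
#' @return List with `vertices` (list of `members` data frame
#'   (`id`, `peak`, `frame_mass`, `score`), `consensus_mass`,
#'   `total_score`), `offsets` (named, translated), `anchor`, `M`
#'   (component span in Da), `ids`.
#' @export
glue <- function(prms, alignments, frame_tol = 0.35) {
  ids <- vapply(prms, function(p) p$id, character(1))
  names(prms) <- ids
  tot <- vapply(prms, function(p) sum(p$peaks$score), numeric(1))
  anchor <- ids[which.max(tot)]

  # maximum-score spanning forest (Kruskal) and frame propagation
  offsets <- stats::setNames(rep(NA_real_, length(ids)), ids)
  offsets[anchor] <- 0
  ord <- order(vapply(alignments, function(a) a$score, numeric(1)),
               decreasing = TRUE)
  comp <- seq_along(ids)                         # spectrum-level union-find
  find_s <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  tree <- logical(length(alignments))
  for (k in ord) {
    a <- alignments[[k]]
    ra <- find_s(match(a$id_a, ids)); rb <- find_s(match(a$id_b, ids))
    if (ra != rb) {
      tree[k] <- TRUE
      comp[ra] <- rb
    }
  }
  # BFS over tree edges from the anchor (handles any traversal order)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (k in which(tree)) {
      a <- alignments[[k]]
      if (!is.na(offsets[a$id_a]) && is.na(offsets[a$id_b])) {
        offsets[a$id_b] <- offsets[a$id_a] + a$shift; changed <- TRUE
      } else if (is.na(offsets[a$id_a]) && !is.na(offsets[a$id_b])) {
        offsets[a$id_a] <- offsets[a$id_b] - a$shift; changed <- TRUE
      }
    }
  }
  offsets[is.na(offsets)] <- 0   # disconnected leftovers anchor themselves

  keep_edge <- vapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    ok <- abs(offsets[a$id_a] + a$shift - offsets[a$id_b]) <= frame_tol
    if (!ok) message("dropping frame-inconsistent alignment ",
                     a$id_a, " ~ ", a$id_b)
    ok
  }, logical(1))

  # global peak table and union-find over peaks
  peak_tab <- do.call(rbind, lapply(ids, function(id) {
    p <- prms[[id]]
    if (nrow(p$peaks) == 0) return(NULL)
    data.frame(id = id, peak = seq_len(nrow(p$peaks)),
               frame_mass = p$peaks$mass + offsets[id],
               score = p$peaks$score, stringsAsFactors = FALSE)
  }))
  key <- paste(peak_tab$id, peak_tab$peak)
  parent <- seq_len(nrow(peak_tab))
  find_p <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  spectra_of <- lapply(seq_len(nrow(peak_tab)), function(i) peak_tab$id[i])
  for (k in which(keep_edge)) {
    a <- alignments[[k]]
    mp <- a$matched_pairs
    for (r in seq_len(nrow(mp))) {
      u <- match(paste(a$id_a, mp$i[r]), key)
      v <- match(paste(a$id_b, mp$j[r]), key)
      ru <- find_p(u); rv <- find_p(v)
      if (ru == rv) next
      if (length(intersect(spectra_of[[ru]], spectra_of[[rv]])) > 0) next
      parent[ru] <- rv
      spectra_of[[rv]] <- c(spectra_of[[rv]], spectra_of[[ru]])
    }
  }
  root <- vapply(seq_len(nrow(peak_tab)), find_p, integer(1))

  # split vertices with frame disagreement, then summarise
  vertices <- list()
  for (r in unique(root)) {
    ix <- which(root == r)
    ix <- ix[order(peak_tab$frame_mass[ix])]
    fm <- peak_tab$frame_mass[ix]
    cl <- cumsum(c(1L, diff(fm) > frame_tol))
    for (sub in split(ix, cl)) {
      m <- peak_tab[sub, , drop = FALSE]
      w <- pmax(m$score, 1e-9)
      vertices[[length(vertices) + 1L]] <- list(
        members = m,
        consensus_mass = sum(m$frame_mass * w) / sum(w),
        total_score = sum(m$score))
    }
  }
  # translate so the leftmost member spectrum starts at 0
  t0 <- min(offsets)
  offsets <- offsets - t0
  for (i in seq_along(vertices)) {
    vertices[[i]]$consensus_mass <- vertices[[i]]$consensus_mass - t0
    vertices[[i]]$members$frame_mass <- vertices[[i]]$members$frame_mass - t0
  }
  M <- max(offsets + vapply(ids, function(id) prms[[id]]$M, numeric(1)))
  ord <- order(vapply(vertices, `[[`, numeric(1), "consensus_mass"))
  list(vertices = vertices[ord], offsets = offsets, anchor = anchor,
       M = M, ids = ids)
}

#' Read the heaviest consensus path of a glued component
#'
#' Builds the contig DAG: vertices ordered by consensus mass, with an
#' edge u -> v whenever some member spectrum has consecutive peaks in u
#' then v. The heaviest path by total vertex score is found by dynamic
#' programming; ties are broken toward more member peaks, then toward
#' the lower consensus mass.
#'
#' @param glued Output of [glue()].
#' @param contig_id Identifier for the contig.
#' @return A `Contig`: list with `contig_id`, `vertices` (data frame
#'   `consensus_mass`, `total_score`, `n_members` along the path),
#'   `path_members` (list of member data frames), `member_ids`
#'   (spectra contributing >= 2 path vertices), `M`, `anchor`.
#' @export
consensus_path <- function(glued, contig_id = "contig") {
  V <- glued$vertices
  nv <- length(V)
  stopifnot(nv > 0)
  vmass <- vapply(V, `[[`, numeric(1), "consensus_mass")
  vscore <- vapply(V, `[[`, numeric(1), "total_score")
  vmemb <- vapply(V, function(v) nrow(v$members), integer(1))
  # vertex index per (spectrum, peak); peak indices follow each
  # spectrum's own mass order, so consecutive peak indices define the
  # spectrum's chain through the vertices
  memb_tab <- do.call(rbind, lapply(seq_len(nv), function(i) {
    data.frame(id = V[[i]]$members$id, peak = V[[i]]$members$peak,
               vertex = i, stringsAsFactors = FALSE)
  }))
  edges <- list()
  for (id in unique(memb_tab$id)) {
    d <- memb_tab[memb_tab$id == id, , drop = FALSE]
    vs <- d$vertex[order(d$peak)]
    if (length(vs) < 2) next
    for (t in seq_len(length(vs) - 1)) {
      u <- vs[t]; v <- vs[t + 1]
      if (u != v && vmass[u] < vmass[v]) {
        edges[[length(edges) + 1L]] <- c(u, v)
      }
    }
  }
  pred <- vector("list", nv)
  for (e in edges) pred[[e[2]]] <- union(pred[[e[2]]], e[1])
  ord <- order(vmass)
  f_score <- vscore; f_memb <- vmemb
  back <- rep(NA_integer_, nv)
  for (v in ord) {
    for (u in pred[[v]]) {
      cs <- f_score[u] + vscore[v]; cm <- f_memb[u] + vmemb[v]
      if (cs > f_score[v] ||
          (cs == f_score[v] && cm > f_memb[v]) ||
          (cs == f_score[v] && cm == f_memb[v] && !is.na(back[v]) &&
             vmass[u] < vmass[back[v]])) {
        f_score[v] <- cs; f_memb[v] <- cm; back[v] <- u
      }
    }
  }
  end <- which.max(f_score)
  path <- end
  while (!is.na(back[path[1]])) path <- c(back[path[1]], path)
  members <- lapply(V[path], `[[`, "members")
  spectra <- table(unlist(lapply(members, function(m) unique(m$id))))
  member_ids <- names(spectra)[spectra >= 2]
  structure(list(
    contig_id = contig_id,
    vertices = data.frame(consensus_mass = vmass[path],
                          total_score = vscore[path],
                          n_members = vmemb[path]),
    path_members = members,
    member_ids = member_ids,
    M = glued$M, anchor = glued$anchor,
    path_score = f_score[end]
  ), class = "Contig")
}

#' @export
print.Contig <- function(x, ...) {
  cat(sprintf("<Contig %s> %d path vertices, %d member spectra, span %.2f Da\n",
              x$contig_id, nrow(x$vertices), length(x$member_ids), x$M))
  invisible(x)
}

#' Consensus meta-contig spectrum of a contig
#'
#' The meta-contig is the contig's consensus PRM spectrum: the path
#' vertices' (consensus mass, total score) pairs. Contigs supported by
#' fewer than `min_component_size` member spectra are discarded
#' (`NULL`).
#'
#' @param contig A `Contig`.
#' @param min_component_size Minimum member spectra, default 2.
#' @return A `MetaContig` (list: `contig_id`, `consensus` data frame
#'   (`mass`, `score`), `n_spectra`, `member_ids`, `span`, `M`) or
#'   `NULL`.
#' @export
to_meta_contig <- function(contig, min_component_size = 2) {
  n_spectra <- length(contig$member_ids)
  if (n_spectra < min_component_size) return(NULL)
  cons <- data.frame(mass = contig$vertices$consensus_mass,
                     score = contig$vertices$total_score)
  structure(list(contig_id = contig$contig_id,
                 consensus = cons,
                 n_spectra = n_spectra,
                 member_ids = contig$member_ids,
                 span = max(cons$mass) - min(cons$mass),
                 M = contig$M),
            class = "MetaContig")
}

#' @export
print.MetaContig <- function(x, ...) {
  cat(sprintf("<MetaContig %s> %d consensus masses, %d spectra, span %.2f Da\n",
              x$contig_id, nrow(x$consensus), x$n_spectra, x$span))
  invisible(x)
}

#' Assemble a spectral network into meta-contigs
#'
#' Runs [glue()], [consensus_path()] and [to_meta_contig()] on every
#' connected component of the network with at least two nodes.
#'
#' @param prms List of `PRMSpectrum` objects (the network's nodes).
#' @param network A `SpectralNetwork` from [build_network()].
#' @param frame_tol Frame tolerance (Da), default 0.35.
#' @param min_component_size Minimum member spectra per meta-contig.
#' @param id_prefix Stem for generated contig ids.
#' @return List of `MetaContig` objects.
#' @export
assemble_network <- function(prms, network, frame_tol = 0.35,
                             min_component_size = 2, id_prefix = "contig") {
  ids <- vapply(prms, function(p) p$id, character(1))
  names(prms) <- ids
  out <- list()
  for (cmp in unique(network$membership)) {
    members <- names(network$membership)[network$membership == cmp]
    if (length(members) < 2) next
    als <- Filter(function(a) a$id_a %in% members && a$id_b %in% members,
                  network$alignments)
    if (length(als) == 0) next
    g <- glue(prms[members], als, frame_tol = frame_tol)
    contig <- consensus_path(g, contig_id = sprintf("%s%04d", id_prefix,
                                                    length(out) + 1L))
    mc <- to_meta_contig(contig, min_component_size)
    if (!is.null(mc)) out[[length(out) + 1L]] <- mc
  }
  out
}
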