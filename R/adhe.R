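# Rule-based detection and classification of adhE-derived genes: length and
# identity/coverage filters, N/C-half gap filtering, alignment-center
# fragment classes, outgroup-based paralog exclusion, sequence similarity
# networks and per-species domain-repertoire states.

#' Select complete-length candidate sequences
#'
#' Keeps sequences whose unaligned length lies in the inclusive range
#' typical of the complete bifunctional enzyme.
#'
#' @param sequences named character vector of protein sequences, or a
#'   [Biostrings::AAStringSet].
#' @param min_len,max_len inclusive length bounds (defaults 800, 1000 aa).
#' @return character vector of sequence ids.
#' @export
select_complete_candidates <- function(sequences, min_len = 800,
                                       max_len = 1000) {
  if (inherits(sequences, "XStringSet")) {
    len <- Biostrings::width(sequences)
    ids <- names(sequences)
  } else {
    len <- nchar(sequences)
    ids <- names(sequences)
  }
  if (!length(len)) return(character())
  if (is.null(ids)) stop("sequences must be named")
  ids[len >= min_len & len <= max_len]
}

#' Filter homology hits by identity and target coverage
#'
#' A query survives if at least one of its hits has identity and target
#' coverage both strictly greater than the thresholds.
#'
#' @param hits data frame with columns `query`, `target`, `identity`,
#'   `coverage` (fractions in [0, 1]).
#' @param min_identity,min_coverage strict lower bounds (defaults 0.45).
#' @return character vector of unique query ids.
#' @export
filter_hits <- function(hits, min_identity = 0.45, min_coverage = 0.45) {
  stopifnot(all(c("query", "identity", "coverage") %in% names(hits)))
  if (any(hits$identity < 0 | hits$identity > 1 |
          hits$coverage < 0 | hits$coverage > 1))
    stop("identity and coverage must be fractions in [0, 1]")
  keep <- hits$identity > min_identity & hits$coverage > min_coverage
  unique(hits$query[keep])
}

#' Extract N- and C-terminal halves of an MSA and filter gappy rows
#'
#' The halves are the first and last `half_cols` columns (they overlap on
#' narrow alignments, which is flagged). Per half, sequences whose gap
#' fraction is strictly greater than `max_gap_frac` are excluded.
#'
#' @param msa character matrix (sequences x columns), gaps as `"-"`.
#' @param half_cols columns per half (default 500).
#' @param max_gap_frac strict gap-fraction bound (default 0.5).
#' @return list with `n_half`, `c_half` (kept sequence ids per half),
#'   `n_cols`, `c_cols` (column indices), `overlap` (logical).
#' @export
split_halves_and_filter <- function(msa, half_cols = 500, max_gap_frac = 0.5) {
  w <- ncol(msa)
  if (w < half_cols) stop("alignment width below half_cols")
  n_cols <- seq_len(half_cols)
  c_cols <- (w - half_cols + 1):w
  overlap <- w < 2 * half_cols
  if (overlap) warning("halves overlap: alignment narrower than 2 * half_cols")
  gapfrac <- function(cols) rowMeans(msa[, cols, drop = FALSE] == "-")
  list(n_half = rownames(msa)[gapfrac(n_cols) <= max_gap_frac],
       c_half = rownames(msa)[gapfrac(c_cols) <= max_gap_frac],
       n_cols = n_cols, c_cols = c_cols, overlap = overlap)
}

.fragment_geometry <- function(row, center_method = "midpoint") {
  idx <- which(row != "-")
  if (!length(idx)) stop("all-gap alignment row")
  center <- switch(center_method,
                   midpoint = floor((idx[1] + idx[length(idx)]) / 2),
                   mean = floor(mean(idx)),
                   stop("unknown center_method"))
  list(length = length(idx), first = idx[1], last = idx[length(idx)],
       center = center)
}

#' Classify one aligned sequence into a fragment class
#'
#' Position rules on the non-gap span: `complete` iff non-gap length is
#' strictly greater than `len_threshold` and the center column lies in
#' `[center_lo, center_hi]`; otherwise `ALDH_only` iff the center is left of
#' `center_lo`, `ADH_only` iff right of `center_hi`, else `incomplete`. The
#' center is the midpoint of the first and last non-gap columns (1-based,
#' rounded half down); `center_method = "mean"` uses the mean non-gap column
#' instead.
#'
#' @param msa character matrix (sequences x columns).
#' @param seq_id row name.
#' @param len_threshold,center_lo,center_hi rule parameters (defaults 800,
#'   400, 900).
#' @param center_method `"midpoint"` (default) or `"mean"`.
#' @return one of `"complete"`, `"ALDH_only"`, `"ADH_only"`, `"incomplete"`.
#' @export
classify_fragment <- function(msa, seq_id, len_threshold = 800,
                              center_lo = 400, center_hi = 900,
                              center_method = "midpoint") {
  if (!seq_id %in% rownames(msa)) stop("sequence not in MSA: ", seq_id)
  g <- .fragment_geometry(msa[seq_id, ], center_method)
  if (g$length > len_threshold && g$center >= center_lo && g$center <= center_hi)
    return("complete")
  if (g$center < center_lo) return("ALDH_only")
  if (g$center > center_hi) return("ADH_only")
  "incomplete"
}

#' Classify every sequence of an MSA into fragment records
#'
#' @inheritParams classify_fragment
#' @param species optional named vector mapping sequence id to species id.
#' @return data frame with columns `id`, `species`, `length`, `first`,
#'   `last`, `center`, `class`.
#' @export
classify_fragments <- function(msa, len_threshold = 800, center_lo = 400,
                               center_hi = 900, center_method = "midpoint",
                               species = NULL) {
  ids <- rownames(msa)
  rows <- lapply(ids, function(id) {
    g <- .fragment_geometry(msa[id, ], center_method)
    data.frame(id = id,
               species = if (is.null(species)) id else unname(species[id]),
               length = g$length, first = g$first, last = g$last,
               center = g$center)
  })
  out <- do.call(rbind, rows)
  out$class <- vapply(ids, function(id)
    classify_fragment(msa, id, len_threshold, center_lo, center_hi,
                      center_method), "")
  out
}

#' Exclude non-family paralogs using an outgroup-rooted gene tree
#'
#' Roots the gene tree on `outgroup_id`, finds the most recent common
#' ancestor of the known complete-gene ids, and keeps only leaves descending
#' from it; leaves outside that clade are returned as non-family paralogs.
#'
#' @param gene_tree [ape::phylo] gene tree containing all ids as leaves.
#' @param outgroup_id leaf used to root the tree.
#' @param complete_ids leaves known to be complete family members.
#' @return list with `kept` (family leaf ids, outgroup excluded), `excluded`
#'   (paralog leaf ids), and `tree` (the rooted tree).
#' @export
exclude_non_adhe <- function(gene_tree, outgroup_id, complete_ids) {
  stopifnot(outgroup_id %in% gene_tree$tip.label,
            all(complete_ids %in% gene_tree$tip.label))
  tr <- ape::root(gene_tree, outgroup = outgroup_id, resolve.root = TRUE)
  tr <- name_nodes(tr)
  mrca <- ape::getMRCA(tr, complete_ids)
  ingroup <- tr$tip.label[descendant_ids(tr, mrca)[descendant_ids(tr, mrca) <= ape::Ntip(tr)]]
  if (outgroup_id %in% ingroup)
    stop("topology-error: outgroup falls inside the MRCA of complete ids")
  list(kept = ingroup,
       excluded = setdiff(tr$tip.label, c(ingroup, outgroup_id)),
       tree = tr)
}

#' Build a sequence similarity network
#'
#' Undirected graph linking sequence pairs whose identity is strictly
#' greater than `threshold`; isolated sequences form singleton components.
#' Self-pairs are ignored with a warning.
#'
#' @param pairwise_identities data frame with columns `id1`, `id2`,
#'   `identity` (fractions in [0, 1]).
#' @param threshold strict identity threshold (e.g. 0.45 or 0.70).
#' @return list with `graph` (an [igraph] graph over all ids),
#'   `membership` (named component index), `components` (list of id sets).
#' @export
build_ssn <- function(pairwise_identities, threshold) {
  stopifnot(all(c("id1", "id2", "identity") %in% names(pairwise_identities)))
  pi <- pairwise_identities
  if (any(pi$identity < 0 | pi$identity > 1))
    stop("identities must be fractions in [0, 1]")
  self <- pi$id1 == pi$id2
  if (any(self)) {
    warning("ignoring ", sum(self), " self-pair(s)")
    pi <- pi[!self, , drop = FALSE]
  }
  ids <- unique(c(pairwise_identities$id1, pairwise_identities$id2))
  edges <- pi[pi$identity > threshold, c("id1", "id2"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  list(graph = g,
       membership = comp$membership,
       components = split(names(comp$membership), comp$membership))
}

.repertoire_catalog <- c("none", "1_complete", "2_complete", "1_ALDH",
                         "1_ADH", "1_incomplete", "complete_plus_ALDH")

#' Assign a domain-repertoire state to every species
#'
#' Maps each species' multiset of fragment classes onto the 7-state catalog
#' (`none`, `1_complete`, `2_complete`, `1_ALDH`, `1_ADH`, `1_incomplete`,
#' `complete_plus_ALDH`). Combinations outside the catalog become `"other"`
#' with a warning. Explicit overrides (e.g. species whose tandem fragments
#' are sequencing artifacts of one complete gene) are applied last.
#'
#' @param fragments data frame with columns `species`, `class` (one row per
#'   gene), e.g. from [classify_fragments()].
#' @param species all species to report (default: those in `fragments`).
#' @param overrides named character vector, species -> state.
#' @return named character vector of states, one per species.
#' @export
assign_repertoire <- function(fragments, species = NULL, overrides = NULL) {
  if (is.null(species)) species <- unique(fragments$species)
  state_of <- function(sp) {
    cls <- fragments$class[fragments$species == sp]
    n <- c(complete = sum(cls == "complete"),
           ALDH = sum(cls == "ALDH_only"),
           ADH = sum(cls == "ADH_only"),
           inc = sum(cls == "incomplete"))
    if (sum(n) == 0) return("none")
    if (n["complete"] == 1 && sum(n) == 1) return("1_complete")
    if (n["complete"] == 2 && sum(n) == 2) return("2_complete")
    if (n["ALDH"] == 1 && sum(n) == 1) return("1_ALDH")
    if (n["ADH"] == 1 && sum(n) == 1) return("1_ADH")
    if (n["inc"] == 1 && sum(n) == 1) return("1_incomplete")
    if (n["complete"] == 1 && n["ALDH"] == 1 && sum(n) == 2)
      return("complete_plus_ALDH")
    "other"
  }
  out <- vapply(species, state_of, "")
  names(out) <- species
  if (any(out == "other"))
    warning("repertoire outside the catalog for: ",
            paste(names(out)[out == "other"], collapse = ", "))
  if (!is.null(overrides)) {
    bad <- setdiff(overrides, c(.repertoire_catalog, "other"))
    if (length(bad)) stop("unknown override state: ", paste(bad, collapse = ", "))
    out[names(overrides)] <- overrides
  }
  out
}
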