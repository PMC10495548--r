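#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration minimizing the criterion
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with branch lengths
#' from the two-point formula. On additive (tree-metric) input the generating
#' topology and exact branch lengths are recovered. Negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch. Ties in
#' the Q criterion are broken by the lexicographically smallest pair of
#' subtree labels, so the output is deterministic.
#'
#' @param dm symmetric distance matrix with labelled rows/columns (>= 3 taxa,
#'   finite entries, zero diagonal).
#' @return newick string for the unrooted tree (trifurcating root).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  if (any(!is.finite(dm))) stop("distance matrix entries must be finite")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  # newick convention: spaces in labels become underscores
  labs <- gsub(" ", "_", rownames(dm))  # newick fragment per active node
  first <- rownames(dm)                 # lexicographic tie-break key per node

  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(dm) > 3) {
    m <- nrow(dm)
    r <- rowSums(dm)
    qmat <- (m - 2) * dm - outer(r, r, "+")
    qmat[upper.tri(qmat, diag = TRUE)] <- Inf
    q_min <- min(qmat)
    cand <- which(qmat <= q_min + 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      # tie-break on the lexicographically smallest pair of subtree labels
      keys <- apply(cand, 1, function(ij) {
        k <- sort(c(first[ij[1]], first[ij[2]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- min(cand[1, ]); j <- max(cand[1, ])
    vi <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dm[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newd <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    newlab <- paste0("(", labs[i], ":", fmt(vi), ",", labs[j], ":", fmt(vj), ")")
    newfirst <- min(first[i], first[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                 c(newd[keep], 0))
    labs <- c(labs[keep], newlab)
    first <- c(first[keep], newfirst)
    dm <- dm2
  }
  # final three-way join
  v1 <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  v2 <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  v3 <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  ord <- order(first)
  parts <- paste0(labs, ":", fmt(v))[ord]
  paste0("(", paste(parts, collapse = ","), ");")
}

#' Assign query COI sequences to species by nearest reference distance
#'
#' Each query passing the pseudogene screen is assigned the species of its
#' minimum-TN93-distance reference when that distance is strictly below
#' \code{threshold}; otherwise it is recorded as \code{"new sp."} with the
#' closest reference noted. Queries overlapping every reference at fewer than
#' \code{min_overlap} comparable sites are left unassigned. Exact ties in the
#' minimum distance are broken by the lexicographically smallest species
#' label and flagged in the \code{tie} column. Distances in the borderline
#' 2--3\% band are flagged for inspection. A neighbor-joining tree over
#' queries plus references is attached for audit.
#'
#' @param queries named character vector of query sequences.
#' @param references named character vector of reference sequences; names are
#'   species labels.
#' @param threshold assignment divergence threshold (strict inequality).
#' @param min_overlap minimum number of comparable sites.
#' @param max_tree_queries cap on the number of queries included in the
#'   audit tree (evenly spaced deterministic subsample beyond it).
#' @return data.frame with one row per query (\code{individual_id},
#'   \code{assigned_species}, \code{closest_reference},
#'   \code{divergence_to_closest}, \code{pseudogene_flag}, \code{tie},
#'   \code{borderline}, \code{reason}); the audit tree (newick) is in
#'   attribute \code{"tree"}.
#' @export
assign_species <- function(queries, references, threshold = 0.02,
                           min_overlap = 300, max_tree_queries = 150) {
  if (length(references) == 0) stop("references must be non-empty")
  if (is.null(names(references))) stop("references must be labelled by species")
  res <- lapply(seq_along(queries), function(qi) {
    q <- queries[[qi]]
    id <- names(queries)[qi]
    cc <- check_coding(q)
    if (!cc$coding) {
      return(data.frame(individual_id = id, assigned_species = NA_character_,
                        closest_reference = NA_character_,
                        divergence_to_closest = NA_real_,
                        pseudogene_flag = TRUE, tie = FALSE,
                        borderline = FALSE, reason = "pseudogene",
                        stringsAsFactors = FALSE))
    }
    d <- vapply(references, function(r) {
      dd <- tn93_distance(q, r)
      if (attr(dd, "sites") < min_overlap) NA_real_ else as.numeric(dd)
    }, numeric(1))
    if (all(is.na(d))) {
      return(data.frame(individual_id = id, assigned_species = NA_character_,
                        closest_reference = NA_character_,
                        divergence_to_closest = NA_real_,
                        pseudogene_flag = FALSE, tie = FALSE,
                        borderline = FALSE,
                        reason = "insufficient overlap or saturated",
                        stringsAsFactors = FALSE))
    }
    dmin <- min(d, na.rm = TRUE)
    cands <- sort(names(d)[!is.na(d) & d <= dmin + 1e-15])
    closest <- cands[1]
    tie <- length(unique(cands)) > 1
    assigned <- if (dmin < threshold) closest else "new sp."
    data.frame(individual_id = id, assigned_species = assigned,
               closest_reference = closest, divergence_to_closest = dmin,
               pseudogene_flag = FALSE, tie = tie,
               borderline = dmin >= 0.02 & dmin < 0.03,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  tree <- NULL
  ok <- which(!out$pseudogene_flag & !is.na(out$divergence_to_closest))
  # the audit tree is for visual inspection; on large cohorts an evenly
  # spaced deterministic subsample of queries keeps it readable and cheap
  if (length(ok) > max_tree_queries) {
    ok <- ok[unique(round(seq(1, length(ok), length.out = max_tree_queries)))]
  }
  audit <- c(references, queries[ok])
  if (length(audit) >= 3) {
    tree <- neighbor_joining(tn93_matrix(audit))
  }
  attr(out, "tree") <- tree
  out
}
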