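#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Distinguishes the two transition types (A<->G, C<->T) and transversions,
#' weighting by base frequencies pooled over both sequences at the retained
#' sites. Sites where either sequence has a gap or an ambiguity code are
#' excluded pairwise.
#'
#' With P1 the proportion of A<->G differences, P2 of C<->T differences, Q of
#' transversions, and pooled frequencies gA..gT (gR = gA+gG, gY = gC+gT):
#' \deqn{d = -k1 log(1 - gR P1/(2 gA gG) - Q/(2 gR))
#'          - k2 log(1 - gY P2/(2 gT gC) - Q/(2 gY))
#'          - k3 log(1 - Q/(2 gR gY))}
#' with k1 = 2 gA gG / gR, k2 = 2 gT gC / gY,
#' k3 = 2 (gR gY - gA gG gY/gR - gT gC gR/gY).
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return distance in substitutions/site, with attribute \code{sites} (number
#'   of retained sites). When any logarithm argument is non-positive the
#'   distance is saturated: \code{NA} is returned with attribute
#'   \code{saturated = TRUE}.
#' @export
tn93_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0) stop("no comparable sites after pairwise deletion")
  a <- a[keep]
  b <- b[keep]
  freq <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
           table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG
  gY <- gC + gT
  diff <- a != b
  pur <- c("A", "G")
  P1 <- sum(diff & a %in% pur & b %in% pur) / n
  P2 <- sum(diff & !a %in% pur & !b %in% pur) / n
  Q <- sum(diff & xor(a %in% pur, b %in% pur)) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (P1 == 0) w1 <- max(w1, 1 - Q / (2 * gR))   # guard 0/0 when gA*gG = 0
  if (P2 == 0) w2 <- max(w2, 1 - Q / (2 * gY))
  if (any(!is.finite(c(w1, w2, w3))) || any(c(w1, w2, w3) <= 0)) {
    return(structure(NA_real_, saturated = TRUE, sites = n))
  }
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  structure(max(d, 0), sites = n, saturated = FALSE)
}

#' Proportion of differing sites (p-distance) with pairwise deletion
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return proportion of differing sites among retained sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable sites after pairwise deletion")
  mean(a[keep] != b[keep])
}

#' TN93 distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector of aligned sequences.
#' @return symmetric matrix with zero diagonal; saturated pairs are \code{NA}.
#' @export
tn93_matrix <- function(seqs) {
  k <- length(seqs)
  m <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
  if (k < 2) return(m)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- as.numeric(tn93_distance(seqs[[i]], seqs[[j]]))
    }
  }
  m
}
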