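## Helpers for working with real crystallographic entries: splitting
## multi-complex asymmetric units and locating the beta_DP subunit from
## its bound nucleotide.

#' Split an asymmetric unit into its F1 complexes
#'
#' Crystal forms with more than one complex per asymmetric unit carry
#' 6 alpha + 6 beta chains (and two of each small subunit) in one model.
#' Chains are grouped into complexes by k-means clustering of the large
#' chain centroids (k = `copies`); each small chain joins the nearest
#' cluster.  Role maps are re-derived per complex.
#'
#' @param model a [StructureModel-class].
#' @param copies number of complexes in the asymmetric unit.
#' @return list of [StructureModel-class] objects of length `copies`.
#' @export
splitComplexes <- function(model, copies = 1L) {
  if (copies <= 1L) return(list(model))
  a <- model@atoms[!model@atoms$het, , drop = FALSE]
  counts <- vapply(split(a$resno, a$chain),
                   function(r) length(unique(r)), integer(1))
  big <- names(counts)[counts >= 100]
  cen <- t(vapply(big, function(ch) colMeans(as.matrix(
    a[a$chain == ch, c("x", "y", "z")])), numeric(3)))
  km <- stats::kmeans(cen, centers = copies, nstart = 10)
  small <- setdiff(names(counts), big)
  assign <- setNames(km$cluster, big)
  for (ch in small) {
    ctr <- colMeans(as.matrix(a[a$chain == ch, c("x", "y", "z")]))
    d <- apply(km$centers, 1, function(p) sum((p - ctr)^2))
    assign[ch] <- which.min(d)
  }
  lapply(seq_len(copies), function(k) {
    keep <- model@atoms$chain %in% names(assign)[assign == k]
    StructureModel(model@atoms[keep, , drop = FALSE],
                   title = paste0(model@title, "-", k))
  })
}

#' Locate beta_DP by its bound ADP
#'
#' The beta_DP subunit carries ADP; the heteroatom records are searched
#' for an ADP group and the beta chain with the smallest atom distance to
#' it is reported.  With several ADP groups (one may also sit on alpha
#' subunits), only distances to beta chains count and the closest
#' beta-ADP assignment wins.
#'
#' @param model a [StructureModel-class].
#' @return chain id of beta_DP.
#' @export
betaDPByNucleotide <- function(model) {
  a <- model@atoms
  adp <- a[a$het & toupper(a$resname) == "ADP", , drop = FALSE]
  if (!nrow(adp)) stop("no ADP heterogroup found; supply dpChain explicitly")
  bCh <- names(model@roleMap)[model@roleMap == "beta"]
  if (!length(bCh)) stop("no beta chains in role map")
  best <- NULL; bestD <- Inf
  groups <- split(adp, paste(adp$chain, adp$resno))
  for (g in groups) {
    G <- as.matrix(g[, c("x", "y", "z")])
    for (ch in bCh) {
      B <- as.matrix(a[a$chain == ch & !a$het & a$elety == "CA",
                       c("x", "y", "z")])
      d2 <- min(outer(rowSums(G^2), rowSums(B^2), `+`) - 2 * G %*% t(B))
      if (d2 < bestD) { bestD <- d2; best <- ch }
    }
  }
  best
}
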