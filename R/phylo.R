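#' @include divergence.R
#' @importFrom ape nj write.tree read.tree prop.part prop.clades
NULL

#' Concatenate region alignments into one supermatrix
#'
#' Joins aligned regions column-wise in the given order, yielding the
#' IR-stripped whole-plastome concatenation when fed the full region set.
#'
#' @param alignments named list of `RegionAlignment` objects sharing taxa
#' @return a `RegionAlignment` named "concatenation"
#' @export
concatenateAlignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- names(alignments[[1]]$rows)
  rows <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) {
      if (!tx %in% names(a$rows)) stop("taxon '", tx, "' missing from '",
                                       a$name, "'")
      a$rows[[tx]]
    }, character(1)), collapse = ""), character(1))
  structure(list(name = "concatenation", rows = rows, L = nchar(rows[[1]])),
            class = "RegionAlignment")
}

#' Site statistics of a concatenated alignment
#'
#' Reports aligned length L, variable positions V, substitutions S, indel
#' events I, total indel length G and percent variability P under the
#' same conventions as [divergenceStats()], plus parsimony-informative
#' sites: columns with at least two base states each present in at least
#' two taxa, gaps ignored (a gap is not a state).
#'
#' @param aln a `RegionAlignment`
#' @return one-row data.frame: aligned_length, variable_positions,
#'   parsimony_informative, substitutions, n_indels, indel_length,
#'   percent_variability
#' @export
alignmentSummary <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("summary requires >= 2 taxa")
  d <- divergenceStats(aln, name = "concatenation")
  pi <- sum(apply(m, 2, function(col) {
    col <- col[col != "-"]
    tb <- table(col)
    sum(tb >= 2L) >= 2L
  }))
  data.frame(aligned_length = d$aligned_length,
             variable_positions = d$variable_positions,
             parsimony_informative = pi,
             substitutions = d$substitutions,
             n_indels = d$n_indels, indel_length = d$indel_length,
             percent_variability = d$percent_variability)
}

#' Jukes-Cantor (JC69) distance matrix
#'
#' Pairwise deletion: for each taxon pair, columns where either row has a
#' gap are excluded; p is the mismatch proportion over the remaining
#' columns and d = -(3/4) log(1 - (4/3) p).
#'
#' @param aln a `RegionAlignment` (or named character vector of rows)
#' @return symmetric numeric distance matrix with zero diagonal
#' @export
jc69Distance <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("distances require >= 2 taxa")
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    if (p >= 0.75)
      stop(sprintf("JC69 distance undefined for pair %s-%s (p = %.3f)",
                   rownames(m)[i], rownames(m)[j], p))
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (ape's implementation); input must be a
#' symmetric matrix with zero diagonal.
#'
#' @param d symmetric distance matrix with taxon dimnames
#' @return an unrooted `phylo` tree
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("neighbor joining requires >= 3 taxa")
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement `nReps` times, rebuilds
#' the JC69 + NJ tree for each replicate, and annotates each internal
#' edge of the full-data tree with the percentage of replicates
#' containing the same bipartition. Fixed `seed` gives identical output.
#'
#' @param aln a `RegionAlignment`
#' @param nReps number of bootstrap replicates (>= 1)
#' @param seed RNG seed
#' @return list with `tree` (phylo; node labels = supports in percent)
#'   and `supports` (numeric vector over internal nodes)
#' @export
bootstrapNJ <- function(aln, nReps = 100L, seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- alignmentMatrix(aln)
  ref <- njTree(jc69Distance(aln))
  set.seed(seed)
  reps <- vector("list", nReps)
  for (b in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- njTree(jc69Distance(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / nReps, 1)
  tree <- ref
  tree$node.label <- as.character(supports)
  list(tree = tree, supports = supports)
}

#' Export helpers for external phylogenetics tools
#'
#' `writeNewickTree` writes Newick with internal-node support labels;
#' `writePhylipAlignment` writes relaxed sequential PHYLIP.
#'
#' @param tree a `phylo` object
#' @param path output path
#' @return `path`, invisibly
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @param aln a `RegionAlignment`
#' @export
writePhylipAlignment <- function(aln, path) {
  rows <- aln$rows
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(rows), nchar(rows[[1]])), con)
  for (nm in names(rows))
    writeLines(paste(gsub("[^A-Za-z0-9_.-]", "_", nm), rows[[nm]]), con)
  invisible(path)
}
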