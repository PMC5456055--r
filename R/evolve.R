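#' @include simulate.R
NULL

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

stateFromAncestor <- function(anc) {
  list(sv = strsplit(as.character(genomeSeq(anc$record)), "")[[1]],
       ft = genomeFeatures(anc$record),
       lsc = lscLength(anc$partition), ir = irLength(anc$partition),
       ssc = sscLength(anc$partition), ssrs = anc$ssrs)
}

statePartition <- function(state) {
  PlastomePartition(state$lsc, state$ir, state$ssc)
}

stateRecord <- function(state, id) {
  GenomeRecord(id, paste(state$sv, collapse = ""), state$ft,
               organism = "synthetic plastome")
}

# shift every coordinate >= from by delta (feature parts and SSR loci);
# valid because indels are confined to the interior of noncoding regions
shiftState <- function(state, from, delta) {
  state$ft$parts <- lapply(state$ft$parts, function(p) {
    p[p >= from] <- p[p >= from] + delta
    p
  })
  if (!is.null(state$ssrs) && nrow(state$ssrs)) {
    state$ssrs$start[state$ssrs$start >= from] <-
      state$ssrs$start[state$ssrs$start >= from] + delta
    state$ssrs$end[state$ssrs$end >= from] <-
      state$ssrs$end[state$ssrs$end >= from] + delta
  }
  pos <- from - 1L # the affected segment is the one containing from-1
  if (pos < state$lsc) state$lsc <- state$lsc + delta
  else if (pos < state$lsc + state$ir + state$ssc &&
           pos >= state$lsc + state$ir) state$ssc <- state$ssc + delta
  else stop("internal: indel outside LSC/SSC")
  state
}

insertBases <- function(state, pos, ins) {
  state$sv <- append(state$sv, ins, after = pos)
  shiftState(state, pos, length(ins))
}

deleteBases <- function(state, pos, len) {
  state$sv <- state$sv[-((pos + 1L):(pos + len))]
  shiftState(state, pos + len, -len) # coords >= pos+len move left
}

overlapsSSR <- function(ssrs, a, b, margin = 1L) {
  if (is.null(ssrs) || !nrow(ssrs)) return(FALSE)
  any(ssrs$start - margin < b & a < ssrs$end + margin)
}

# evolve one genome state along one branch; every sequence-modifying
# action is recorded in application order so a branch can be replayed
evolveBranch <- function(state, bl, config) {
  actions <- list()
  act <- function(a) actions[[length(actions) + 1L]] <<- a
  l <- state$lsc; ir <- state$ir; ssc <- state$ssc
  iraStart <- l + ir + ssc
  map <- contextMap(stateRecord(state, "node"), statePartition(state))

  # substitutions: Poisson per rate region, JC base changes, IR mirrored
  for (ri in seq_len(nrow(map))) {
    width <- map$end[ri] - map$start[ri]
    mult <- regionMultiplier(config, map$name[ri], map$category[ri])
    k <- stats::rpois(1L, bl * width * mult)
    if (!k) next
    for (p0 in sample(seq.int(map$start[ri], map$end[ri] - 1L), k,
                      replace = TRUE)) {
      # SSR loci evolve by slippage only; point changes would fragment
      # the repeat tract
      if (overlapsSSR(state$ssrs, p0, p0 + 1L)) next
      # junction-flank bases stay pinned so the planted IR remains the
      # uniquely maximal exact reverse-complement pair
      if (p0 == l - 1L || p0 == l + ir || p0 == iraStart - 1L) next
      old <- state$sv[p0 + 1L]
      if (!old %in% BASES) next
      newb <- sample(setdiff(BASES, old), 1L)
      state$sv[p0 + 1L] <- newb
      mp <- NA_integer_
      if (p0 >= l && p0 < l + ir) mp <- iraStart + (l + ir - 1L - p0)
      else if (p0 >= iraStart) mp <- l + ir - 1L - (p0 - iraStart)
      if (!is.na(mp)) state$sv[mp + 1L] <- COMP[[newb]]
      act(list(type = "sub", region = map$name[ri], pos = p0, from = old,
               to = newb, mirror_pos = mp))
    }
  }

  # indels: noncoding regions wholly inside LSC or SSC
  nc <- map[map$category %in% c("intron", "spacer") &
              (map$end <= l | (map$start >= l + ir & map$end <= iraStart)), ,
            drop = FALSE]
  nc <- nc[order(-nc$start), , drop = FALSE] # downstream first: shifts
  for (ri in seq_len(nrow(nc))) {           # cannot invalidate later rows
    width <- nc$end[ri] - nc$start[ri]
    k <- stats::rpois(1L, bl * config$indelRate * width)
    if (!k) next
    for (e in seq_len(k)) {
      len <- min(stats::rgeom(1L, config$indelGeomP) + 1L, 10L)
      isIns <- stats::runif(1L) < 0.5
      lo <- nc$start[ri] + 1L
      hi <- nc$end[ri] - 1L - (if (isIns) 0L else len)
      if (hi < lo) next
      ok <- FALSE
      for (try in 1:20) {
        pos <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
        a <- pos; b <- pos + (if (isIns) 0L else len)
        if (!overlapsSSR(state$ssrs, a, b)) { ok <- TRUE; break }
      }
      if (!ok) next
      if (isIns) {
        ins <- sample(BASES, len, replace = TRUE)
        state <- insertBases(state, pos, ins)
        act(list(type = "ins", region = nc$name[ri], pos = pos,
                 seq = paste(ins, collapse = "")))
      } else {
        act(list(type = "del", region = nc$name[ri], pos = pos, len = len,
                 seq = paste(state$sv[(pos + 1L):(pos + len)],
                             collapse = "")))
        state <- deleteBases(state, pos, len)
      }
    }
  }

  # SSR slippage: whole units gained/lost at the locus end (non-IR loci)
  if (!is.null(state$ssrs) && nrow(state$ssrs)) {
    ord <- order(-state$ssrs$start)
    for (si in ord) {
      s <- state$ssrs[si, ]
      inIR <- (s$start >= state$lsc && s$start < state$lsc + state$ir) ||
        s$start >= state$lsc + state$ir + state$ssc
      if (inIR) next
      nev <- stats::rpois(1L, config$slipRate * s$n_units * bl)
      if (!nev) next
      net <- sum(sample(c(-1L, 1L), nev, replace = TRUE))
      net <- max(net, 3L - s$n_units)
      if (net == 0L) next
      u <- s$unit_len
      if (net > 0L) {
        ins <- strsplit(strrep(s$motif, net), "")[[1]]
        act(list(type = "ins", region = s$context, pos = s$end,
                 seq = paste(ins, collapse = ""), slippage = TRUE))
        state <- insertBases(state, s$end, ins)
      } else {
        len <- -net * u
        act(list(type = "del", region = s$context, pos = s$end - len,
                 len = len,
                 seq = paste(state$sv[(s$end - len + 1L):s$end],
                             collapse = ""), slippage = TRUE))
        state <- deleteBases(state, s$end - len, len)
      }
      state$ssrs$n_units[si] <- s$n_units + net
    }
  }
  list(state = state, actions = actions)
}

#' Replay recorded branch actions on a parent sequence
#'
#' Applies the recorded substitutions/insertions/deletions of one branch,
#' in order, to a parent sequence; used to verify that the simulator's
#' coordinate bookkeeping reproduces each child genome exactly.
#'
#' @param parentSeq character scalar parent genome sequence
#' @param actions the branch's recorded action list
#' @return character scalar child sequence
#' @export
replayBranchActions <- function(parentSeq, actions) {
  sv <- strsplit(parentSeq, "")[[1]]
  for (a in actions) {
    if (a$type == "sub") {
      sv[a$pos + 1L] <- a$to
      if (!is.na(a$mirror_pos)) sv[a$mirror_pos + 1L] <- COMP[[a$to]]
    } else if (a$type == "ins") {
      sv <- append(sv, strsplit(a$seq, "")[[1]], after = a$pos)
    } else if (a$type == "del") {
      sv <- sv[-((a$pos + 1L):(a$pos + a$len))]
    }
  }
  paste(sv, collapse = "")
}

#' Simulate annotated plastomes along a known tree
#'
#' Builds the ancestor from the configuration and evolves it along the
#' configured tree: per-branch Poisson substitution counts with
#' per-region rate multipliers and Jukes-Cantor base changes, noncoding
#' indels with geometric lengths, SSR unit slippage, and perfect IR
#' homogenization (every IR mutation mirrored between the copies). All
#' randomness derives from the configured seed.
#'
#' @param config a `SimConfig` from [simConfig()]
#' @return list with `records` (leaf [GenomeRecord-class] objects),
#'   `ancestor`, and `truth` (ground-truth manifest: tree, per-leaf
#'   partitions and SSR loci, region multipliers, per-branch actions,
#'   intermediate node sequences for replay checks)
#' @export
simulatePlastomes <- function(config = simConfig()) {
  set.seed(config$seed)
  anc <- buildAncestor(config)
  tr <- ape::read.tree(text = config$tree)
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  states <- list(); actions <- list(); parentSeq <- list()
  leaves <- list(); leafInfo <- list()
  recurse <- function(node, state) {
    for (ei in which(tr$edge[, 1] == node)) {
      child <- tr$edge[ei, 2]
      res <- evolveBranch(state, tr$edge.length[ei], config)
      label <- if (child <= nTip) tr$tip.label[child]
      else paste0("node", child)
      actions[[label]] <<- res$actions
      parentSeq[[label]] <<- paste(state$sv, collapse = "")
      if (child <= nTip) {
        leaves[[label]] <<- stateRecord(res$state, label)
        leafInfo[[label]] <<- list(
          lsc = res$state$lsc, ir = res$state$ir, ssc = res$state$ssc,
          ssrs = res$state$ssrs)
      } else {
        recurse(child, res$state)
      }
    }
  }
  recurse(root, stateFromAncestor(anc))
  ancMap <- contextMap(anc$record, anc$partition)
  mult <- data.frame(
    name = ancMap$name, category = ancMap$category,
    multiplier = vapply(seq_len(nrow(ancMap)), function(i)
      regionMultiplier(config, ancMap$name[i], ancMap$category[i]),
      numeric(1)), stringsAsFactors = FALSE)
  mult <- mult[!duplicated(mult$name), , drop = FALSE]
  list(records = leaves[tr$tip.label], ancestor = anc,
       truth = list(tree = config$tree, taxa = tr$tip.label,
                    partitions = leafInfo, multipliers = mult,
                    actions = actions, parent_seqs = parentSeq,
                    seeds = config$ssrSeeds))
}

#' Write a simulated dataset to disk
#'
#' One GenBank flat file per leaf genome plus a JSON ground-truth
#' manifest (`truth.json`).
#'
#' @param sim result of [simulatePlastomes()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in sim$records)
    writeGenBank(rec, file.path(dir, paste0(genomeId(rec), ".gb")))
  truth <- sim$truth
  truth$parent_seqs <- NULL # sequences live in the GenBank files
  truth$partitions <- lapply(truth$partitions, function(x)
    list(lsc = x$lsc, ir = x$ir, ssc = x$ssc,
         ssrs = x$ssrs[, c("context", "motif", "unit_len", "n_units")]))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
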