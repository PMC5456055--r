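# independent brute-force oracles used to cross-check the implementation

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# character-count GC oracle
oracleGC <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  v <- v[v %in% c("A", "C", "G", "T")]
  floor(100 * sum(v %in% c("G", "C")) / length(v) * 100 + 0.5) / 100
}

# exhaustive enumerator of maximal perfect tandem runs, filtered by the
# unit-count minima, smallest-unit (primitive motif) preference, and the
# smaller-unit-wins trimming policy
oracleSSRs <- function(s, thresholds = plastomeCompare::ssrThresholds()) {
  v <- strsplit(toupper(s), "")[[1]]
  n <- length(v)
  ok <- v %in% c("A", "C", "G", "T")
  eqAt <- function(i, u) i >= 1L && i + u <= n &&
    ok[i] && ok[i + u] && v[i] == v[i + u]
  prim <- function(motif) {
    u <- nchar(motif)
    for (d in seq_len(max(u - 1L, 0L))) {
      if (u %% d) next
      if (paste(rep(substr(motif, 1, d), u / d), collapse = "") == motif)
        return(FALSE)
    }
    TRUE
  }
  cand <- list()
  for (u in 1:6) {
    for (i in seq_len(max(n - u, 0L))) {
      if (!eqAt(i, u)) next         # no periodicity evidence at i
      if (eqAt(i - 1L, u)) next     # not the start of a maximal tract
      j <- i + u
      while (j + 1L <= n && eqAt(j + 1L - u, u)) j <- j + 1L
      len <- j - i + 1L
      if (len %/% u >= thresholds[[as.character(u)]]) {
        motif <- paste(v[i:(i + u - 1L)], collapse = "")
        if (prim(motif))
          cand[[length(cand) + 1L]] <- data.frame(
            motif = motif, unit_len = u, start = i - 1L,
            end = i - 1L + len, n_units = len %/% u, length = len,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(data.frame(motif = character(), unit_len = integer(),
                      start = integer(), end = integer(),
                      n_units = integer(), length = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$unit_len, cand$start), , drop = FALSE]
  acc <- cand[0, , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    cur <- cand[r, , drop = FALSE]
    repeat {
      ov <- which(acc$start < cur$end & cur$start < acc$end)
      if (!length(ov)) break
      cur$start <- max(acc$end[ov])
      if (cur$start >= cur$end) break
      cur$length <- cur$end - cur$start
      cur$n_units <- cur$length %/% cur$unit_len
      cur$motif <- paste(v[(cur$start + 1L):(cur$start + cur$unit_len)],
                         collapse = "")
    }
    if (cur$start >= cur$end) next
    if (cur$n_units < thresholds[[as.character(cur$unit_len)]]) next
    if (!prim(cur$motif)) next
    acc <- rbind(acc, cur)
  }
  acc <- acc[order(acc$start), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

# plain column-scan divergence oracle
oracleDivergence <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  S <- 0L; gapcols <- 0L
  for (j in seq_len(L)) {
    col <- m[, j]
    if (any(col == "-")) gapcols <- gapcols + 1L
    else if (length(unique(col)) > 1L) S <- S + 1L
  }
  keys <- character(0); lens <- integer(0)
  for (i in seq_len(nrow(m))) {
    j <- 1L
    while (j <= L) {
      if (m[i, j] == "-") {
        k <- j
        while (k < L && m[i, k + 1L] == "-") k <- k + 1L
        key <- paste(j, k)
        if (!key %in% keys) { keys <- c(keys, key); lens <- c(lens, k - j + 1L) }
        j <- k + 1L
      } else j <- j + 1L
    }
  }
  list(L = L, S = S, I = length(keys), G = sum(lens), V = S + gapcols,
       P = floor(100 * (S + length(keys)) / L * 100 + 0.5) / 100)
}

# random gapped alignment: mutate and poke gap runs into copies of a seed
randomAlignment <- function(nrow = 4L, L = 40L) {
  base <- strsplit(randomDNA(L), "")[[1]]
  rows <- vapply(seq_len(nrow), function(i) {
    v <- base
    nmut <- sample(0:4, 1)
    if (nmut) {
      at <- sample(L, nmut)
      v[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
    }
    for (g in seq_len(sample(0:2, 1))) {
      glen <- sample(1:3, 1)
      at <- sample(L - glen, 1)
      v[at:(at + glen - 1L)] <- "-"
    }
    paste(v, collapse = "")
  }, character(1))
  stats::setNames(rows, paste0("t", seq_len(nrow)))
}
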