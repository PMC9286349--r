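## Independent oracles used across the suite. These deliberately avoid the
## package's own index machinery: occurrence search goes through plain
## substring comparison or Biostrings::vmatchPattern, and the pairing /
## hierarchy logic is re-implemented from scratch.

## naive scan: all occurrences of `query` in a named character vector of
## sequences, 0-based half-open, ordered by (entry, start)
naiveScanOccurrences <- function(seqs, query) {
  out <- list()
  qn <- nchar(query)
  for (j in seq_along(seqs)) {
    s <- seqs[[j]]
    w <- nchar(s)
    if (w < qn) next
    starts <- which(vapply(seq_len(w - qn + 1L), function(i)
      substr(s, i, i + qn - 1L) == query, logical(1L)))
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(
        accession = names(seqs)[j], entry = j, start = starts - 1L,
        end = starts - 1L + qn, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(accession = character(), entry = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## vmatchPattern-backed occurrence search over an AAStringSet subject
vmatchOccurrences <- function(subject, query) {
  m <- Biostrings::vmatchPattern(query, subject)
  counts <- vapply(m, length, integer(1L))
  starts <- unlist(lapply(m, BiocGenerics::start), use.names = FALSE)
  ends <- unlist(lapply(m, BiocGenerics::end), use.names = FALSE)
  if (is.null(starts)) starts <- ends <- integer()
  data.frame(entry = rep(seq_along(m), counts), start = starts - 1L,
             end = as.integer(ends), stringsAsFactors = FALSE)
}

## stringi (ICU) backed occurrence search over a character vector; a third,
## fully independent match engine, fast enough for large randomized runs
striOccurrences <- function(seqs, query) {
  loc <- stringi::stri_locate_all_fixed(seqs, query, overlap = TRUE)
  counts <- vapply(loc, function(m) sum(!is.na(m[, 1L])), integer(1L))
  starts <- unlist(lapply(loc, function(m) m[!is.na(m[, 1L]), 1L]),
                   use.names = FALSE)
  if (is.null(starts)) starts <- integer()
  data.frame(entry = rep(seq_along(seqs), counts),
             start = as.integer(starts) - 1L,
             end = as.integer(starts) - 1L + nchar(query),
             stringsAsFactors = FALSE)
}

## brute-force splice classification, fully independent of the package's
## mapper: Biostrings matching plus from-scratch pairing and hierarchy.
## Returns list(category, explanations) where explanations is a canonical
## sorted data.frame (category, splitPoint, leftEntry, leftStart,
## rightEntry, rightStart, interveningLen).
oracleClassify <- function(peptide, seqs, maxIntervening = 25,
                           engine = c("stri", "vmatch")) {
  engine <- match.arg(engine)
  n <- nchar(peptide)
  if (engine == "vmatch") {
    subject <- Biostrings::AAStringSet(seqs)
    occ <- function(q) vmatchOccurrences(subject, q)
  } else {
    occ <- function(q) striOccurrences(seqs, q)
  }

  canon <- function(df) {
    df <- df[order(df$splitPoint, df$leftEntry, df$leftStart,
                   df$rightEntry, df$rightStart, method = "radix",
                   na.last = FALSE), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  emptyEx <- data.frame(category = character(), splitPoint = integer(),
                        leftEntry = integer(), leftStart = integer(),
                        rightEntry = integer(), rightStart = integer(),
                        interveningLen = integer(),
                        stringsAsFactors = FALSE)

  full <- occ(peptide)
  if (nrow(full) > 0L) {
    return(list(category = "NONSPLICED", explanations = canon(data.frame(
      category = "NONSPLICED", splitPoint = NA_integer_,
      leftEntry = full$entry, leftStart = full$start,
      rightEntry = NA_integer_, rightStart = NA_integer_,
      interveningLen = NA_integer_, stringsAsFactors = FALSE))))
  }

  cis <- list()
  trans <- list()
  for (sp in seq_len(n - 1L)) {
    L <- occ(substr(peptide, 1L, sp))
    R <- occ(substr(peptide, sp + 1L, n))
    if (nrow(L) == 0L || nrow(R) == 0L) next
    for (i in seq_len(nrow(L))) {
      for (j in seq_len(nrow(R))) {
        if (L$entry[i] == R$entry[j]) {
          gapN <- R$start[j] - L$end[i]
          gapR <- L$start[i] - R$end[j]
          if (gapN >= 0L && gapN <= maxIntervening)
            cis[[length(cis) + 1L]] <- data.frame(
              category = "CIS_NORMAL", splitPoint = sp,
              leftEntry = L$entry[i], leftStart = L$start[i],
              rightEntry = R$entry[j], rightStart = R$start[j],
              interveningLen = gapN, stringsAsFactors = FALSE)
          if (gapR >= 0L && gapR <= maxIntervening)
            cis[[length(cis) + 1L]] <- data.frame(
              category = "CIS_REVERSE", splitPoint = sp,
              leftEntry = L$entry[i], leftStart = L$start[i],
              rightEntry = R$entry[j], rightStart = R$start[j],
              interveningLen = gapR, stringsAsFactors = FALSE)
        } else {
          trans[[length(trans) + 1L]] <- data.frame(
            category = "TRANS", splitPoint = sp,
            leftEntry = L$entry[i], leftStart = L$start[i],
            rightEntry = R$entry[j], rightStart = R$start[j],
            interveningLen = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cis) > 0L)
    return(list(category = "CIS",
                explanations = canon(do.call(rbind, cis))))
  if (length(trans) > 0L)
    return(list(category = "TRANS",
                explanations = canon(do.call(rbind, trans))))
  list(category = "NONE", explanations = emptyEx)
}

## package classification mapped onto the oracle's canonical explanation form
packageClassifyCanonical <- function(peptide, index, params) {
  cl <- classifyPeptide(peptide, index, params)
  ex <- explanations(cl)
  accs <- accessions(index)
  df <- data.frame(category = ex$category, splitPoint = ex$splitPoint,
                   leftEntry = match(ex$leftAccession, accs),
                   leftStart = ex$leftStart,
                   rightEntry = match(ex$rightAccession, accs),
                   rightStart = ex$rightStart,
                   interveningLen = ex$interveningLen,
                   stringsAsFactors = FALSE)
  df <- df[order(df$splitPoint, df$leftEntry, df$leftStart, df$rightEntry,
                 df$rightStart, method = "radix", na.last = FALSE), ,
           drop = FALSE]
  rownames(df) <- NULL
  list(category = category(cl), explanations = df)
}

## independently coded hypergeometric upper tail P(X >= m)
hypergeomTailOracle <- function(m, K, N, n) {
  i <- m:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## random proteome as a plain named character vector (19-letter alphabet)
randomSeqs <- function(nProteins, maxLen, minLen = 20) {
  alpha <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "K", "L", "M", "N",
                     "P", "Q", "R", "S", "T", "V", "W", "Y"), character())
  lens <- sample(seq.int(minLen, maxLen), nProteins, replace = TRUE)
  setNames(vapply(lens, function(l)
    paste(sample(alpha, l, replace = TRUE), collapse = ""), character(1L)),
    sprintf("P%03d", seq_len(nProteins)))
}

## noiseless, jitter-free spectrum of a peptide (perfect self-match)
perfectSpectrum <- function(peptide, id = paste0("perfect_", peptide),
                            charge = 2L) {
  frag <- theoreticalFragments(peptide)
  Spectrum(id, (peptideMass(peptide) + charge * 1.00727646688) / charge,
           charge, cbind(mz = unname(frag),
                         intensity = rep(100, length(frag))))
}
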