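#' Action and non-action seed words
#'
#' The ten seed words against which every content word of a picture
#' description is compared: five action concepts and five non-action
#' concepts. Embodied-cognition theory predicts that impaired motor function
#' biases speech away from action concepts, so the similarity distributions
#' to these seeds carry medication-state information.
#'
#' @return character vector of 10 seed words, with a `"pool"` attribute
#'   marking each as `"action"` or `"nonaction"`.
#' @examples
#' seedWords()
#' @export
seedWords <- function() {
  w <- c("action", "act", "move", "play", "energetic",
         "inaction", "sleep", "rest", "sit", "wait")
  attr(w, "pool") <- rep(c("action", "nonaction"), each = 5)
  w
}

#' Extract content words from a transcript
#'
#' Returns the tokens tagged noun or verb, order-preserving and with
#' duplicates kept; similarity features are computed over exactly these
#' words.
#'
#' @param transcript a [Transcript-class].
#' @return character vector (possibly empty) of content words.
#' @export
extractContentWords <- function(transcript) {
  stopifnot(is(transcript, "Transcript"))
  tok <- tokens(transcript)
  tok$word[tok$pos %in% c("noun", "verb")]
}

#' Cosine similarity between two embedded words
#'
#' Larger values mean "more similar"; the measure is invariant to positive
#' rescaling of either vector.
#'
#' @param word,seed words to compare (must be in the table's vocabulary).
#' @param table embedding matrix with one row per word (rownames = words).
#' @return cosine similarity in \[-1, 1\].
#' @examples
#' tab <- rbind(a = c(1, 0), b = c(1, 1))
#' cosineSimilarity("a", "b", tab)   # 1/sqrt(2)
#' @export
cosineSimilarity <- function(word, seed, table) {
  u <- .lookupVector(table, word)
  v <- .lookupVector(table, seed)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero embedding vector")
  sum(u * v) / (nu * nv)
}

.lookupVector <- function(table, word) {
  if (!word %in% rownames(table))
    stop("word not in embedding vocabulary: ", word)
  as.numeric(table[word, ])
}

#' Semantic feature vector: seed-similarity descriptors plus word count
#'
#' For each of the 10 seed words, computes the cosine similarities between
#' the seed and every in-vocabulary content word (nouns and verbs) of the
#' transcript, and summarizes that similarity distribution with 6
#' descriptors (median, percentiles 10 and 90, skewness, kurtosis, IQR),
#' named in the style `"PLAY (pct10)"`. One additional feature `"nw"` counts
#' all transcript tokens. Total: 10 x 6 + 1 = 61 features.
#'
#' Out-of-vocabulary content words are skipped, so the similarity features
#' depend only on in-vocabulary words; OOV tokens still count toward `"nw"`.
#'
#' @param transcript a [Transcript-class].
#' @param table embedding matrix (rows = words; e.g. from
#'   [generateToyEmbeddings()] or [readWordVectors()]).
#' @param seeds seed word vector, default [seedWords()]; all must be in the
#'   embedding vocabulary.
#' @param minWords minimum number of in-vocabulary content words; below it
#'   the 60 similarity features are `NA` with a warning (`"nw"` is still
#'   reported).
#' @return named numeric vector of length 61.
#' @export
semanticFeatureVector <- function(transcript, table, seeds = seedWords(),
                                  minWords = 3) {
  stopifnot(is(transcript, "Transcript"))
  if (!all(seeds %in% rownames(table)))
    stop("seed word(s) missing from the embedding vocabulary: ",
         paste(setdiff(seeds, rownames(table)), collapse = ", "))
  descNames <- c("pct50", "pct10", "pct90", "sk", "kur", "iqr")
  nm <- c(as.vector(outer(descNames, toupper(seeds),
                          function(d, s) sprintf("%s (%s)", s, d))), "nw")
  out <- rep(NA_real_, length(nm))
  names(out) <- nm
  out["nw"] <- nrow(tokens(transcript))
  words <- extractContentWords(transcript)
  words <- words[words %in% rownames(table)]
  if (length(words) < minWords) {
    warning(sprintf(
      "only %d in-vocabulary content words (need %d); similarity features set to NA",
      length(words), minWords))
    return(out)
  }
  mat <- table[words, , drop = FALSE]
  mat <- mat / sqrt(rowSums(mat^2))
  for (s in seeds) {
    v <- .lookupVector(table, s)
    v <- v / sqrt(sum(v^2))
    sims <- as.numeric(mat %*% v)
    out[sprintf("%s (%s)", toupper(s), descNames)] <-
      summarizeDistribution(sims, set = "six")
  }
  out
}

#' Read and write word vectors in text format
#'
#' The standard word-vector text format: one `word v1 v2 ... vd` line per
#' word, space-separated.
#'
#' @param path file path.
#' @return `readWordVectors()`: a numeric matrix with words as rownames.
#' @export
readWordVectors <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  dims <- lengths(parts) - 1L
  if (!length(parts) || any(dims != dims[1]) || dims[1] < 1)
    stop("malformed word-vector file (inconsistent dimensions): ", path)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1])))
  rownames(mat) <- vapply(parts, `[[`, character(1), 1)
  if (any(!is.finite(mat))) stop("non-numeric entries in: ", path)
  mat
}

#' @rdname readWordVectors
#' @param table embedding matrix with words as rownames.
#' @export
writeWordVectors <- function(table, path) {
  lines <- vapply(seq_len(nrow(table)), function(i)
    paste(rownames(table)[i],
          paste(formatC(table[i, ], format = "g", digits = 10),
                collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}
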