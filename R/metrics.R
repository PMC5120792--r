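# Intelligibility metrics: recognition accuracy and chance level, confusion
# matrices with seriation, word accuracy from a minimum-edit alignment,
# mel-cepstral distortion, and a centroid classifier standing in for human
# listeners at desk scale.

#' Recognition accuracy
#'
#' `Acc = R/N`: the fraction of responses exactly matching the ground
#' truth.
#'
#' @param truth,response equal-length label vectors.
#' @return Scalar accuracy in \[0, 1\].
#' @export
accuracy <- function(truth, response) {
  if (length(truth) == 0) stop("empty label vectors")
  if (length(truth) != length(response)) stop("length mismatch")
  mean(as.character(truth) == as.character(response))
}

#' Chance level for a balanced forced-choice test
#'
#' `Acc_chance = 1/C` for `C` equally represented categories.
#'
#' @param C number of categories (>= 1).
#' @return `1/C`.
#' @export
chance_level <- function(C) {
  if (C < 1) stop("C must be >= 1")
  1 / C
}

#' Confusion matrix with row-normalized proportions
#'
#' Rows are ground truth, columns responses. The per-row error is one minus
#' the diagonal proportion.
#'
#' @param truth,response label vectors; all values must be in `labels`.
#' @param labels category order (default: sorted union of `truth`).
#' @return A `confusion_matrix`: `counts`, `proportions`, `row_error`,
#'   `labels`, `n`.
#' @export
confusion_matrix <- function(truth, response, labels = sort(unique(truth))) {
  truth <- as.character(truth); response <- as.character(response)
  unknown <- setdiff(unique(c(truth, response)), labels)
  if (length(unknown)) stop("labels not in label set: ",
                            paste(unknown, collapse = ", "))
  tf <- factor(truth, levels = labels)
  rf <- factor(response, levels = labels)
  counts <- table(truth = tf, response = rf)
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(truth = labels, response = labels))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = props,
                 row_error = 1 - diag(props), labels = labels,
                 n = length(truth)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<confusion_matrix: %d categories, N = %d>\n",
              length(x$labels), x$n))
  m <- cbind(round(x$proportions, digits), error = round(x$row_error, digits))
  print(m)
  invisible(x)
}

# band-diagonal seriation objective: sum p_ij * w(|i-j|), w decreasing
seriation_objective <- function(P, perm) {
  Q <- P[perm, perm, drop = FALSE]
  C <- nrow(Q)
  w <- 1 / (1 + abs(outer(seq_len(C), seq_len(C), "-")))
  sum(Q * w)
}

permutations_all <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_all(n - 1)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

#' Seriation of a confusion matrix
#'
#' Reorders rows and columns by the same permutation so that large
#' proportions concentrate near the diagonal, exposing confusion blocks.
#' The objective `sum p_ij / (1 + |i - j|)` is maximized exactly by
#' exhaustive search for up to `exact_max` categories, and by greedy
#' insertion refined with 2-opt passes beyond that. The objective is never
#' smaller than under the input ordering; counts are only permuted, never
#' changed.
#'
#' @param cm a [confusion_matrix].
#' @param exact_max largest category count searched exhaustively
#'   (default 8).
#' @return The reordered `confusion_matrix`, with the applied permutation
#'   in `$ordering` (indices into the original label order).
#' @export
seriate <- function(cm, exact_max = 8) {
  P <- cm$proportions
  C <- nrow(P)
  if (C < 2) stop("need at least 2 categories")
  S <- (P + t(P)) / 2  # symmetrized affinity for ordering
  if (C <= exact_max) {
    perms <- permutations_all(C)
    scores <- vapply(perms, function(p) seriation_objective(P, p), 0)
    best <- perms[[which.max(scores)]]
  } else {
    # greedy insertion by affinity, then 2-opt refinement
    best <- order(-rowSums(S))[1]
    remaining <- setdiff(seq_len(C), best)
    while (length(remaining)) {
      nxt <- remaining[which.max(S[best[length(best)], remaining])]
      best <- c(best, nxt)
      remaining <- setdiff(remaining, nxt)
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      cur <- seriation_objective(P, best)
      for (i in seq_len(C - 1)) for (j in (i + 1):C) {
        cand <- best
        cand[i:j] <- rev(cand[i:j])
        sc <- seriation_objective(P, cand)
        if (sc > cur + 1e-12) { best <- cand; cur <- sc; improved <- TRUE }
      }
    }
  }
  if (seriation_objective(P, best) < seriation_objective(P, seq_len(C)))
    best <- seq_len(C)
  out <- cm
  out$counts <- cm$counts[best, best, drop = FALSE]
  out$proportions <- cm$proportions[best, best, drop = FALSE]
  out$row_error <- cm$row_error[best]
  out$labels <- cm$labels[best]
  out$ordering <- best
  out
}

#' Word accuracy from a minimum-edit alignment
#'
#' Aligns hypothesis to reference tokens with unit-cost
#' substitution/deletion/insertion dynamic programming (ties prefer
#' substitutions over insertion+deletion pairs) and reports
#' `WAcc = (N - S - D - I)/N`. Character inputs of length one are
#' tokenized: lowercased, punctuation stripped, split on whitespace.
#'
#' @param ref,hyp token vectors, or single strings to tokenize.
#' @return List with `wacc`, `S`, `D`, `I`, `N`.
#' @export
word_accuracy <- function(ref, hyp) {
  tok <- function(x) {
    if (is.character(x) && length(x) == 1 &&
        (grepl("\\s", x) || nchar(trimws(x)) == 0)) {
      x <- tolower(gsub("[[:punct:]]", "", x))
      x <- trimws(x)
      x <- if (nchar(x) == 0) character(0) else strsplit(x, "\\s+")[[1]]
    }
    as.character(x)
  }
  r <- tok(ref); h <- tok(hyp)
  n <- length(r); m <- length(h)
  if (n == 0) stop("empty reference")
  # DP over (0..n) x (0..m); cost and operation counts
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sub <- D[i, j] + (r[i] != h[j])
    del <- D[i, j + 1] + 1L
    ins <- D[i + 1, j] + 1L
    D[i + 1, j + 1] <- min(sub, del, ins)
  }
  # backtrace, preferring match/substitution on ties
  i <- n; j <- m; S <- 0L; Del <- 0L; Ins <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (r[i] != h[j])) {
      S <- S + (r[i] != h[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L) {
      Del <- Del + 1L; i <- i - 1
    } else {
      Ins <- Ins + 1L; j <- j - 1
    }
  }
  list(wacc = (n - S - Del - Ins) / n, S = S, D = Del, I = Ins, N = n)
}

#' Mel-cepstral distortion (dB)
#'
#' Frame-averaged `(10/ln 10) * sqrt(2 * sum_{m>=1} (a_m - b_m)^2)`.
#' Coefficient 0 (gain) is excluded, so the measure is gain-invariant.
#'
#' @param a,b [mel_cepstrogram]s or equal-shaped coefficient matrices.
#' @return Mean distortion in dB.
#' @export
mel_cepstral_distortion <- function(a, b) {
  A <- if (inherits(a, "mel_cepstrogram")) a$frames else as.matrix(a)
  B <- if (inherits(b, "mel_cepstrogram")) b$frames else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  d2 <- rowSums((A[, -1, drop = FALSE] - B[, -1, drop = FALSE])^2)
  mean(10 / log(10) * sqrt(2 * d2))
}

#' Nearest-centroid classification of synthesized stimuli
#'
#' A machine proxy for the listener test: each stimulus (the steady-state
#' mel-cepstra of a synthesized item) is assigned the class whose template
#' mean cepstrum is closest in mel-cepstral distortion. Ties break toward
#' the first label in the template order.
#'
#' @param stimuli list of mel-cepstral matrices (or [mel_cepstrogram]s),
#'   one per stimulus.
#' @param templates named list of class template matrices (one or more
#'   rows of mel-cepstra per class; rows are averaged).
#' @return Character vector of predicted labels.
#' @export
centroid_classify <- function(stimuli, templates) {
  if (length(templates) == 0) stop("empty template set")
  cent <- lapply(templates, function(tm) {
    M <- if (inherits(tm, "mel_cepstrogram")) tm$frames else as.matrix(tm)
    colMeans(M)
  })
  labs <- names(cent)
  vapply(stimuli, function(st) {
    M <- if (inherits(st, "mel_cepstrogram")) st$frames else as.matrix(st)
    v <- colMeans(M)
    d <- vapply(cent, function(ce)
      mel_cepstral_distortion(matrix(v, 1), matrix(ce, 1)), 0)
    labs[which.min(d)]
  }, "")
}

#' Score report for a forced-choice identification test
#'
#' @param truth,response label vectors.
#' @param labels category set (defines `C` for the chance level).
#' @return A `score_report`: overall and per-category accuracy, chance
#'   level, and the confusion matrix.
#' @export
score_report <- function(truth, response, labels = sort(unique(truth))) {
  cm <- confusion_matrix(truth, response, labels)
  per_cat <- diag(cm$proportions)
  structure(list(acc = accuracy(truth, response), per_category = per_cat,
                 chance = chance_level(length(labels)), confusion = cm),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report: Acc = %.3f (chance %.3f, %d categories)>\n",
              x$acc, x$chance, length(x$per_category)))
  invisible(x)
}
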