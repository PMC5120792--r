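# Intelligibility metrics: accuracy, chance level, confusion matrices and
# seriation, word accuracy, mel-cepstral distortion, centroid classifier.

test_that("accuracy counts exact matches", {
  expect_equal(accuracy(letters[1:5], letters[1:5]), 1.0)
  truth <- rep(c("a", "b"), 25)
  resp <- truth; resp[1:5] <- "x"
  expect_equal(accuracy(truth, resp), 45 / 50)
  set.seed(30)
  t2 <- sample(letters[1:4], 200, replace = TRUE)
  r2 <- sample(letters[1:4], 200, replace = TRUE)
  brute <- 0
  for (i in seq_along(t2)) brute <- brute + (t2[i] == r2[i])
  expect_equal(accuracy(t2, r2), brute / 200)
  expect_error(accuracy(character(0), character(0)), "empty")
})

test_that("chance level is 1/C and matches a uniform guesser", {
  expect_equal(chance_level(10), 0.10)
  expect_equal(chance_level(16), 0.0625)
  expect_equal(chance_level(1), 1.0)
  expect_error(chance_level(0), ">= 1")
  set.seed(131)
  n <- 1e5
  truth <- sample(1:7, n, replace = TRUE)
  guess <- sample(1:7, n, replace = TRUE)
  emp <- accuracy(truth, guess)
  se <- sqrt((1 / 7) * (6 / 7) / n)
  expect_lt(abs(emp - 1 / 7), 3 * se)
})

test_that("confusion matrices: identity, forced confusion, conservation", {
  labs <- c("a", "b", "v")
  cm <- confusion_matrix(rep(labs, 4), rep(labs, 4), labs)
  expect_equal(cm$proportions, diag(3), ignore_attr = TRUE)
  expect_true(all(cm$row_error == 0))

  truth <- c(rep("b", 6), rep("a", 3))
  resp <- c(rep("v", 6), rep("a", 3)) # every /b/ answered /v/
  cm2 <- confusion_matrix(truth, resp, labs)
  expect_equal(cm2$proportions["b", "v"], 1.0)
  expect_equal(cm2$row_error[["b"]], 1.0)
  expect_equal(sum(cm2$counts), 9)
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), labs), "label")
})

test_that("seriation restores scrambled block structure (vs exhaustive optimum)", {
  # block-diagonal target: two confusion clusters
  P <- matrix(0.02, 6, 6)
  P[1:3, 1:3] <- 0.25
  P[4:6, 4:6] <- 0.25
  diag(P) <- 0.4
  P <- P / rowSums(P)
  counts <- round(P * 100)
  build_cm <- function(counts, labs) {
    truth <- rep(labs, rowSums(counts))
    resp <- unlist(lapply(seq_len(nrow(counts)), function(i)
      rep(labs, counts[i, ])))
    confusion_matrix(truth, resp, labs)
  }
  labs <- letters[1:6]
  set.seed(32)
  perm <- sample(6)
  cm_scr <- build_cm(counts[perm, perm], labs)
  out <- seriate(cm_scr)
  # oracle: exhaustive search over all 720 orders
  obj <- function(P, p) emasynth:::seriation_objective(P, p)
  best <- max(vapply(emasynth:::permutations_all(6),
                     function(p) obj(cm_scr$proportions, p), 0))
  expect_equal(obj(cm_scr$proportions, out$ordering), best)
  expect_gte(obj(cm_scr$proportions, out$ordering),
             obj(cm_scr$proportions, 1:6))
  # conservation: counts permuted, never changed
  expect_equal(sort(as.vector(out$counts)), sort(as.vector(cm_scr$counts)))
  expect_equal(sum(out$counts), sum(cm_scr$counts))
  # blocks contiguous again: the labels of the first original cluster
  # (scrambled label j carries original row perm[j]) end up adjacent
  cluster1 <- labs[perm %in% 1:3]
  pos <- match(cluster1, out$labels)
  expect_equal(diff(range(pos)), 2)
})

test_that("greedy seriation path (C > exact_max) also improves the objective", {
  set.seed(33)
  C <- 10
  P <- matrix(runif(C * C, 0, 0.05), C, C)
  blocks <- list(1:4, 5:7, 8:10)
  for (bl in blocks) P[bl, bl] <- P[bl, bl] + 0.3
  P <- P / rowSums(P)
  counts <- round(P * 200)
  labs <- letters[1:C]
  truth <- rep(labs, rowSums(counts))
  resp <- unlist(lapply(seq_len(C), function(i) rep(labs, counts[i, ])))
  perm <- sample(C)
  cm <- confusion_matrix(factor(truth, levels = labs[perm]),
                         factor(resp, levels = labs[perm]), labs[perm])
  out <- seriate(cm, exact_max = 8)
  obj <- emasynth:::seriation_objective
  expect_gte(obj(cm$proportions, out$ordering), obj(cm$proportions, 1:C))
})

test_that("word accuracy handles substitutions, deletions and insertions", {
  perfect <- word_accuracy(c("le", "chat", "dort", "tres", "bien"),
                           c("le", "chat", "dort", "tres", "bien"))
  expect_equal(perfect$wacc, 1.0)
  expect_equal(perfect$S + perfect$D + perfect$I, 0)

  del <- word_accuracy("le chat dort", "le dort")
  expect_equal(del$D, 1)
  expect_equal(del$wacc, 2 / 3)

  ins <- word_accuracy("le chat dort", "le petit chat dort")
  expect_equal(ins$I, 1)
  expect_equal(ins$wacc, 2 / 3)

  sub <- word_accuracy("le chat dort", "le chien dort")
  expect_equal(sub$S, 1)

  # tokenization: case and punctuation are ignored
  expect_equal(word_accuracy("Le chat dort.", "le chat dort")$wacc, 1.0)
  expect_error(word_accuracy("", "a b"), "empty")
})

test_that("word accuracy totals agree with the edit distance (independent oracle)", {
  set.seed(34)
  vocab <- letters[1:6]
  for (i in 1:25) {
    r <- sample(vocab, sample(3:10, 1), replace = TRUE)
    h <- sample(vocab, sample(1:10, 1), replace = TRUE)
    res <- word_accuracy(r, h)
    # oracle: adist on strings with one character per token
    dist <- drop(utils::adist(paste(r, collapse = ""),
                              paste(h, collapse = "")))
    expect_equal(res$S + res$D + res$I, dist)
    expect_equal(res$wacc, (res$N - dist) / res$N)
  }
})

test_that("mel-cepstral distortion is gain-invariant and matches a naive loop", {
  set.seed(35)
  A <- matrix(rnorm(10 * 25), 10, 25)
  expect_equal(mel_cepstral_distortion(A, A), 0)
  B <- A; B[, 1] <- B[, 1] + 5 # gain-only difference
  expect_equal(mel_cepstral_distortion(A, B), 0)

  C <- A + matrix(rnorm(250, sd = 0.3), 10, 25)
  naive <- mean(vapply(1:10, function(t)
    10 / log(10) * sqrt(2 * sum((A[t, 2:25] - C[t, 2:25])^2)), 0))
  expect_equal(mel_cepstral_distortion(A, C), naive, tolerance = 1e-12)
  expect_error(mel_cepstral_distortion(A, C[1:5, ]), "mismatch")
})

test_that("centroid classifier separates classes and breaks ties by label order", {
  set.seed(36)
  centers <- list(x = c(0, rep(1, 24)), y = c(0, rep(-1, 24)))
  templates <- lapply(centers, function(ce)
    matrix(rep(ce, 5), 5, 25, byrow = TRUE))
  expect_equal(centroid_classify(list(templates$x), templates), "x")

  stim <- lapply(1:60, function(i) {
    lab <- if (i %% 2) "x" else "y"
    matrix(centers[[lab]], 3, 25, byrow = TRUE) +
      matrix(rnorm(75, sd = 0.05), 3, 25)
  })
  pred <- centroid_classify(stim, templates)
  truth <- ifelse(seq_len(60) %% 2 == 1, "x", "y")
  expect_gte(accuracy(truth, pred), 0.99)

  # exact tie: first label in template order wins
  mid <- matrix(c(0, rep(0, 24)), 1, 25)
  expect_equal(centroid_classify(list(mid), templates), "x")
  expect_error(centroid_classify(list(mid), list()), "empty")
})

test_that("accuracy equals the diagonal mass of the confusion matrix", {
  set.seed(37)
  labs <- letters[1:5]
  truth <- sample(labs, 300, replace = TRUE)
  resp <- ifelse(runif(300) < 0.7, truth, sample(labs, 300, replace = TRUE))
  cm <- confusion_matrix(truth, resp, labs)
  expect_equal(accuracy(truth, resp), sum(diag(cm$counts)) / cm$n)
  rep <- score_report(truth, resp, labs)
  expect_equal(rep$acc, sum(diag(cm$counts)) / cm$n)
  expect_equal(rep$chance, 0.2)
})
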