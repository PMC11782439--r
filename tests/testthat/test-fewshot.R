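test_that("reference sampling is balanced, leave-one-out and deterministic", {
  man <- fake_manifest(50)
  refs <- sample_references(man, "m_001", k_per_class = 2, seed = 9)
  expect_identical(nrow(refs), 4L)
  expect_identical(as.vector(table(refs$label)[c("melanoma", "nevus")]), c(2L, 2L))
  expect_false("m_001" %in% refs$id)
  # melanoma references presented first
  expect_identical(refs$label, c("melanoma", "melanoma", "nevus", "nevus"))
  expect_identical(refs$id, sample_references(man, "m_001", 2, seed = 9)$id)
  expect_false(identical(refs$id, sample_references(man, "m_001", 2, seed = 10)$id))
})

test_that("sampling depends on the query id, not just the seed", {
  man <- fake_manifest(20)
  r1 <- sample_references(man, "m_001", 2, seed = 5)
  r2 <- sample_references(man, "m_002", 2, seed = 5)
  expect_false(identical(r1$id, r2$id))
})

test_that("sampling errors name the deficient class and missing queries", {
  man <- fake_manifest(3)
  expect_error(sample_references(man, "m_001", k_per_class = 3, seed = 1),
               "class 'melanoma' has only 2")
  expect_error(sample_references(man, "zzz", 1, seed = 1), "not found")
})

test_that("leave-one-out and class balance hold across random draws", {
  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(4:30, 1)
      man <- fake_manifest(n, sample(4:30, 1))
      qid <- sample(man$id, 1)
      k <- sample.int(3, 1)
      if (min(class_counts(man) - (man[man$id == qid, ]$label == LABELS)) < k) next
      refs <- sample_references(man, qid, k, seed = sample.int(1e6, 1))
      expect_false(qid %in% refs$id)
      expect_identical(as.vector(table(factor(refs$label, LABELS))), rep(as.integer(k), 2L))
      expect_false(anyDuplicated(refs$id) > 0)
    }
  })
})

test_that("composed messages put labeled references first and the query last", {
  q <- random_image(8, 8, seed = 1)
  refs <- lapply(2:5, function(s) random_image(8, 8, seed = s))
  task <- array_task(q, "melanoma", refs, c("melanoma", "melanoma", "nevus", "nevus"),
                     k_per_class = 2)
  msg <- compose_prompt(task)
  expect_s3_class(msg, "cvd_message")
  expect_length(msg$parts, 5L)
  kinds <- vapply(msg$parts, `[[`, character(1), "kind")
  expect_identical(kinds, c(rep("reference", 4), "query"))
  labs <- vapply(msg$parts[1:4], `[[`, character(1), "label")
  expect_identical(labs, c("melanoma", "melanoma", "nevus", "nevus"))
  expect_null(msg$parts[[5]]$label) # query label never disclosed
  expect_match(msg$text, "most similar")
})

test_that("request digests track message content", {
  q <- random_image(8, 8, seed = 1)
  refs <- lapply(2:3, function(s) random_image(8, 8, seed = s))
  mk <- function(qi) array_task(qi, "melanoma", refs, c("melanoma", "nevus"))
  expect_identical(compose_prompt(mk(q))$request_digest,
                   compose_prompt(mk(q))$request_digest)
  q2 <- q
  q2[1, 1, 1] <- 1 - q2[1, 1, 1]
  expect_false(identical(compose_prompt(mk(q))$request_digest,
                         compose_prompt(mk(q2))$request_digest))
  # disclosed labels are part of the digest
  t_swapped <- array_task(q, "melanoma", refs, c("nevus", "melanoma"))
  expect_false(identical(compose_prompt(mk(q))$request_digest,
                         compose_prompt(t_swapped)$request_digest))
})

test_that("tasks reject self-references and unbalanced reference sets", {
  q <- tibble::tibble(id = "a", label = "melanoma", path = "x", condition = "none")
  refs <- tibble::tibble(id = c("a", "b"), label = c("melanoma", "nevus"),
                         path = "x", condition = "none")
  imgs <- lapply(1:2, function(s) random_image(4, 4, seed = s))
  expect_error(
    few_shot_task(q, refs, random_image(4, 4), imgs, k_per_class = 1),
    "among its own references")
  refs2 <- tibble::tibble(id = c("b", "c"), label = c("nevus", "nevus"),
                          path = "x", condition = "none")
  expect_error(
    few_shot_task(q, refs2, random_image(4, 4), imgs, k_per_class = 1),
    "references per class")
})

test_that("answers parse into clean, recovered and failed statuses", {
  p <- parse_response("Melanoma. The lesion shows irregular red streaks.")
  expect_identical(p$predicted_label, "melanoma")
  expect_identical(p$parse_status, "clean")
  expect_identical(p$explanation, "The lesion shows irregular red streaks.")

  p <- parse_response("This appears benign (nevus), given uniform pink coloration.")
  expect_identical(p$predicted_label, "nevus")
  expect_identical(p$parse_status, "recovered")

  expect_identical(parse_response("Cannot determine.")$parse_status, "failed")
  expect_identical(parse_response("")$parse_status, "failed")
  # contradictory mentions of both classes fail rather than guess
  p <- parse_response("Either melanoma or a benign nevus.")
  expect_identical(p$parse_status, "failed")
  expect_true(is.na(p$predicted_label))
  # keyword matching is on token boundaries and case-insensitive
  expect_identical(parse_response("MALIGNANT features")$predicted_label, "melanoma")
})

test_that("classify retries transport errors and reports exhausted retries", {
  q <- random_image(8, 8, seed = 1)
  refs <- lapply(2:3, function(s) random_image(8, 8, seed = s))
  task <- array_task(q, "melanoma", refs, c("melanoma", "nevus"))

  calls <- 0L
  flaky <- function(message) {
    calls <<- calls + 1L
    if (calls < 3L) cvdfewshot:::transport_error("socket reset")
    list(raw_text = "Melanoma. Recovered after retries.", backend_id = "flaky")
  }
  pred <- classify(task, flaky, max_retries = 2, retry_wait = 0)
  expect_identical(pred$predicted_label, "melanoma")
  expect_identical(calls, 3L)

  dead <- function(message) cvdfewshot:::transport_error("down")
  pred <- classify(task, dead, max_retries = 1, retry_wait = 0)
  expect_identical(pred$parse_status, "failed")
  expect_match(pred$note, "transport error after 2 attempt")

  broken <- function(message) list(nonsense = TRUE)
  expect_error(classify(task, broken), "contract violation")
})
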