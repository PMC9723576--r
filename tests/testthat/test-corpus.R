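test_that("JSONL sessions are read, grouped and ordered; bad records reported", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  lines <- c(
    '{"session_id":"a","seq":2,"role":"C","text":"hello there"}',
    '{"session_id":"b","seq":1,"role":"H","text":"hi"}',
    '{"session_id":"a","seq":1,"role":"H","text":"I feel low"}',
    '{"session_id":"c","seq":1,"role":"H","text":"x"}',
    '{"session_id":"c","seq":2,"role":"X","text":"bad role"}',
    '{"session_id":"c","seq":3,"text":"no role field"}'
  )
  writeLines(lines, f)
  out <- read_sessions(f)
  expect_named(out, c("a", "b", "c"))
  expect_equal(out$a$n_exchanges, 2)
  expect_equal(out$a$messages$seq, c(1, 2))
  expect_equal(out$a$messages$role, c("help_seeker", "counselor"))
  errs <- attr(out, "errors")
  expect_setequal(errs$reason, c("unknown_role", "missing_field:role"))
  expect_error(read_sessions("/nonexistent/zz.jsonl"), "no such file")
})

test_that("sessions survive a write/read round trip", {
  s <- toy_session("rt", n_h = 3, n_c = 3)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_sessions(list(s), f)
  back <- read_sessions(f)[[1]]
  expect_equal(back$messages, s$messages)
})

test_that("default tokenizer lowercases, strips punctuation, is idempotent", {
  expect_equal(tokenize("I want to die so badly"),
               c("i", "want", "to", "die", "so", "badly"))
  expect_equal(tokenize(""), character())
  expect_equal(tokenize("abc, abc."), c("abc", "abc"))
  expect_equal(tokenize("It's not that I want to die."),
               c("it", "s", "not", "that", "i", "want", "to", "die"))
  # idempotence on its own output joined by spaces
  for (txt in c("Hello, world! 123", "a--b  c...d", "Ena; dio, TRIA!")) {
    once <- tokenize(txt)
    expect_identical(tokenize(paste(once, collapse = " ")), once)
  }
  # pluggable segmenter is used verbatim
  expect_equal(tokenize("ab", tokenizer = function(x) strsplit(x, "")[[1]]),
               c("a", "b"))
})

test_that("blocks partition help-seeker messages in order", {
  s <- toy_session("p", n_h = 25, n_c = 25)
  b <- segment_blocks(s, block_size = 10)
  expect_length(b, 3)
  expect_equal(vapply(b, function(x) length(x$message_seqs), 0), c(10, 10, 5))
  expect_equal(vapply(b, `[[`, TRUE, "is_partial"), c(FALSE, FALSE, TRUE))
  expect_equal(vapply(b, `[[`, 0, "block_index"), c(0, 1, 2))
  # partition property: union of block messages = all help-seeker messages
  hs <- s$messages$seq[s$messages$role == "help_seeker"]
  got <- unlist(lapply(b, `[[`, "message_seqs"))
  expect_identical(got, hs)
  expect_false(any(duplicated(got)))

  expect_length(segment_blocks(toy_session("q", n_h = 10), block_size = 10), 1)
  one <- segment_blocks(toy_session("r", n_h = 9), block_size = 10)
  expect_length(one, 1)
  expect_true(one[[1]]$is_partial)
  expect_equal(length(one[[1]]$message_seqs), 9)

  no_h <- session("z", 1:2, c("C", "C"), c("a", "b"))
  expect_length(segment_blocks(no_h), 0)
})

test_that("counselor text joins block tokens only on request", {
  s <- session("m", 1:4, c("H", "C", "H", "C"),
               c("alpha beta", "gamma", "delta", "epsilon"))
  b <- segment_blocks(s, block_size = 10)
  expect_setequal(b[[1]]$tokens, c("alpha", "beta", "delta"))
  b2 <- segment_blocks(s, block_size = 10, include_counselor_tokens = TRUE)
  expect_true("gamma" %in% b2[[1]]$tokens)
})

test_that("session inclusion criteria exclude short and no-prior-block sessions", {
  short <- toy_session("short", n_h = 5, n_c = 4)   # 9 total
  ok <- toy_session("ok", n_h = 5, n_c = 5)         # 10 total
  flt <- filter_sessions(list(short, ok))
  expect_equal(vapply(flt$kept, `[[`, "", "session_id"), "ok")
  expect_equal(flt$excluded$reason, "too_short")

  # labeled path: first ISSB at block 0 => no_pissb
  mk_blocks <- function(sid, pattern) {
    s <- toy_session(sid, n_h = 10 * length(pattern))
    label_blocks(segment_blocks(s), iss_status = pattern)
  }
  b_bad <- mk_blocks("bad", c(TRUE, FALSE))
  b_good <- mk_blocks("good", c(FALSE, FALSE, TRUE))
  flt2 <- filter_sessions(list(toy_session("bad", n_h = 20),
                               toy_session("good", n_h = 30)),
                          labeled_blocks = c(b_bad, b_good))
  expect_equal(flt2$excluded$reason, "no_pissb")
  expect_equal(flt2$excluded$session_id, "bad")
  # kept + excluded = input, disjoint
  expect_setequal(c(vapply(flt2$kept, `[[`, "", "session_id"),
                    flt2$excluded$session_id), c("bad", "good"))
})

test_that("TF-IDF vocabulary scores and truncation follow the stated variant", {
  mk <- function(id, txt) session(id, 1, "H", txt)
  # 3 docs; A: tf 4 in one doc; B: tf 1 in one doc; ubiquitous word everywhere
  docs <- list(mk("1", "ubiq aword aword aword aword"),
               mk("2", "ubiq bword"),
               mk("3", "ubiq"))
  v <- select_vocabulary(docs, k = 1)
  expect_equal(v$word, "aword")
  expect_equal(v$score[1], 4 * log(3 / 1))
  # ubiquitous word has idf 0 and loses to any positive-score word
  v2 <- select_vocabulary(docs, k = 2)
  expect_setequal(v2$word, c("aword", "bword"))
  # no truncation when k covers everything
  expect_warning(v3 <- select_vocabulary(docs, k = 100), "retaining all")
  expect_setequal(v3$word, c("aword", "bword", "ubiq"))
  expect_equal(v3$score[v3$word == "ubiq"], 0)
})

test_that("growing k never drops a previously retained word", {
  set.seed(11)
  docs <- lapply(1:8, function(i)
    session(i, 1, "H", paste(sample(letters[1:15], 30, replace = TRUE), collapse = " ")))
  prev <- character()
  for (k in c(2, 5, 9, 14)) {
    v <- select_vocabulary(docs, k = k)
    expect_true(all(prev %in% v$word))
    prev <- v$word
  }
})
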