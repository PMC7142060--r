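finished_job_fixture <- function(k = 2, seed = 81) {
  store <- cad_store(tempfile("store"))
  user <- operator_user()
  fx <- stored_series_fixture(store, planted_spec(k, seed = seed),
                              user = user)
  register_plugin(store, plugin_manifest("toy-blob", "1.0",
                                         toy_plugin_runtime(200, 3)))
  enqueue_job(store, "toy-blob", fx$entry$series_uid, user)
  job <- run_next_job(store)
  stopifnot(job$status == "finished", length(job$results) == k)
  list(store = store, job = job, user = user)
}

test_that("only complete four-class assignments are accepted", {
  fx <- finished_job_fixture(2)
  jid <- fx$job$job_id

  ok <- record_feedback(fx$store, jid,
                        feedback_entry("reader1",
                                       list(`1` = "known_TP", `2` = "FP")))
  expect_length(ok$feedback, 1)

  expect_error(record_feedback(fx$store, jid,
                               feedback_entry("r", list(`1` = "known_TP"))),
               "unclassified candidate rank\\(s\\): 2")
  expect_error(record_feedback(fx$store, jid,
                               feedback_entry("r", list(`1` = "known_TP",
                                                        `2` = "sub_TP"))),
               "unknown feedback class")
  expect_error(record_feedback(fx$store, jid,
                               feedback_entry("r", list(`1` = "FP", `2` = "FP",
                                                        `3` = "FP"))),
               "unknown candidate rank\\(s\\): 3")
  # rejected entries leave the job unchanged
  expect_length(load_job(fx$store, jid)$feedback, 1)
})

test_that("false-negative marks are bounds-checked against the volume", {
  fx <- finished_job_fixture(1, seed = 82)
  jid <- fx$job$job_id
  good <- feedback_entry("r", list(`1` = "pending"),
                         false_negatives = list(c(5, 5, 5)))
  expect_length(record_feedback(fx$store, jid, good)$feedback, 1)
  # the fixture volume is 40 x 40 x 24
  bad <- feedback_entry("r", list(`1` = "pending"),
                        false_negatives = list(c(5, 5, 24)))
  expect_error(record_feedback(fx$store, jid, bad), "outside volume dims")
  expect_error(record_feedback(fx$store, jid,
                               feedback_entry("r", list(`1` = "pending"),
                                              list(c(1, 2)))),
               "outside volume dims")
})

test_that("feedback requires a finished job", {
  store <- cad_store(tempfile("store"))
  user <- operator_user()
  fx <- stored_series_fixture(store, planted_spec(1, seed = 83),
                              user = user)
  register_plugin(store, plugin_manifest("toy-blob", "1.0",
                                         toy_plugin_runtime(200, 3)))
  job <- enqueue_job(store, "toy-blob", fx$entry$series_uid, user)
  expect_error(record_feedback(store, job$job_id,
                               feedback_entry("r", list(`1` = "FP"))),
               "finished")
})

test_that("summaries count classes flatly and respect job grouping", {
  fx <- finished_job_fixture(3, seed = 84)
  jid <- fx$job$job_id
  record_feedback(fx$store, jid,
                  feedback_entry("r1", list(`1` = "known_TP", `2` = "FP",
                                            `3` = "pending"),
                                 false_negatives = list(c(1, 1, 1))))
  record_feedback(fx$store, jid,
                  feedback_entry("r2", list(`1` = "known_TP",
                                            `2` = "missed_TP",
                                            `3` = "FP")))
  tab <- summarize_feedback(list_jobs(fx$store))
  expect_identical(tab$known_TP, 2L)
  expect_identical(tab$missed_TP, 1L)
  expect_identical(tab$FP, 2L)
  expect_identical(tab$pending, 1L)
  expect_identical(tab$fn_marks, 1L)
  expect_identical(tab$entries, 2L)
  # totals conserve: classes sum to candidates with feedback
  expect_identical(tab$known_TP + tab$missed_TP + tab$FP + tab$pending,
                   2L * 3L)
  expect_identical(nrow(summarize_feedback(list())), 0L)
})

test_that("summaries add over arbitrary partitions of the entries", {
  # random job documents; oracle: flat recount over the raw entries
  set.seed(17)
  classes <- c("known_TP", "missed_TP", "FP", "pending")
  jobs <- lapply(1:50, function(i) {
    n_cand <- sample(0:5, 1)
    n_fb <- sample(0:3, 1)
    list(job_id = paste0("j", i),
         plugin_id = sample(c("alpha", "beta"), 1),
         status = "finished",
         results = lapply(seq_len(n_cand), function(r) list(rank = r)),
         feedback = lapply(seq_len(n_fb), function(u) {
           list(user = paste0("u", u),
                per_candidate = as.list(stats::setNames(
                  sample(classes, n_cand, replace = TRUE),
                  seq_len(n_cand))),
                false_negatives = rep(list(c(0, 0, 0)),
                                      sample(0:2, 1)))
         }))
  })
  whole <- summarize_feedback(jobs)
  flat <- unlist(lapply(jobs, function(j) {
    unlist(lapply(j$feedback, function(e) unlist(e$per_candidate)))
  }))
  for (cls in classes) {
    expect_identical(sum(whole[[cls]]), sum(flat == cls))
  }
  for (trial in 1:100) {
    pick <- runif(length(jobs)) < runif(1)
    a <- summarize_feedback(jobs[pick])
    b <- summarize_feedback(jobs[!pick])
    for (cls in c(classes, "fn_marks", "entries")) {
      expect_identical(sum(a[[cls]]) + sum(b[[cls]]), sum(whole[[cls]]))
    }
  }
})
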