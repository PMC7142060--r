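job_store_fixture <- function(n_series = 1, seeds = 1:n_series,
                              threshold = 200, min_voxels = 3) {
  store <- cad_store(tempfile("store"))
  user <- operator_user()
  fixtures <- lapply(seeds, function(sd) {
    stored_series_fixture(store, planted_spec(2, seed = sd), user = user)
  })
  register_plugin(store, plugin_manifest(
    "toy-blob", "1.0", toy_plugin_runtime(threshold, min_voxels)))
  list(store = store, user = user, fixtures = fixtures)
}

test_that("jobs are dispatched first-in first-out and strictly sequentially", {
  fx <- job_store_fixture(3, seeds = 31:33)
  ids <- vapply(fx$fixtures, function(f) f$entry$series_uid, "")
  jobs <- lapply(ids, function(u) enqueue_job(fx$store, "toy-blob", u,
                                              fx$user))
  expect_true(all(vapply(jobs, `[[`, "", "status") == "in_queue"))

  done <- lapply(1:3, function(i) run_next_job(fx$store))
  # oracle: FIFO simulation — completion order equals enqueue order
  expect_identical(vapply(done, `[[`, "", "job_id"),
                   vapply(jobs, `[[`, "", "job_id"))
  # sequential: execution windows never overlap
  for (i in 1:2) {
    expect_lte(done[[i]]$timing$ended, done[[i + 1]]$timing$started)
  }
  expect_error(run_next_job(fx$store), "no job in queue")
})

test_that("enqueue enforces plugin registration and domain access", {
  fx <- job_store_fixture(1, seeds = 41)
  uid <- fx$fixtures[[1]]$entry$series_uid
  expect_error(enqueue_job(fx$store, "nope", uid, fx$user),
               "unknown plugin")
  outsider <- user_context("eve", domains = "elsewhere", roles = "operator")
  expect_error(enqueue_job(fx$store, "toy-blob", uid, outsider),
               "access denied.*domain")
  admin <- user_context("root", domains = character(), roles = "admin")
  expect_identical(enqueue_job(fx$store, "toy-blob", uid, admin)$status,
                   "in_queue")
})

test_that("prepared work directories honour the sandbox contract", {
  fx <- job_store_fixture(1, seeds = 51)
  uid <- fx$fixtures[[1]]$entry$series_uid
  job <- enqueue_job(fx$store, "toy-blob", uid, fx$user)
  wd <- prepare_job_inputs(fx$store, job$job_id)

  files <- list.files(wd, recursive = TRUE, full.names = TRUE)
  expect_false(any(vapply(files, has_dicom_magic, TRUE)))
  expect_true(file.exists(file.path(wd, "series", "0", "volume.mhd")))
  expect_true(dir.exists(file.path(wd, "out")))

  # volume.raw byte length = nx*ny*nz*element size
  vol <- fx$fixtures[[1]]$volume
  expect_equal(file.size(file.path(wd, "series", "0", "volume.raw")),
               prod(dim(vol$data)) * 2)

  # metadata.txt tag set = (selected list ∩ header) minus PHI list
  lines <- readLines(file.path(wd, "series", "0", "metadata.txt"))
  keys <- sub(" = .*$", "", lines)
  selected <- radcad:::selected_plugin_tags()
  header <- names(fx$fixtures[[1]]$metadata$key_values)
  expect_setequal(keys, setdiff(intersect(selected, header),
                                load_phi_tags()))
  expect_length(intersect(keys, load_phi_tags()), 0)
  # and no PHI value leaks either
  expect_false(any(grepl("SYNTHETIC|SYN[0-9]{6}|19000101",
                         readLines(file.path(wd, "series", "0",
                                             "metadata.txt")))))
})

test_that("failing plugins mark the job failed and the queue proceeds", {
  fx <- job_store_fixture(1, seeds = 61)
  uid <- fx$fixtures[[1]]$entry$series_uid
  register_plugin(fx$store, plugin_manifest(
    "boom", "1.0", function(work_dir) stop("detector exploded")))
  register_plugin(fx$store, plugin_manifest(
    "no-results", "1.0", function(work_dir) invisible(NULL)))
  register_plugin(fx$store, plugin_manifest(
    "bad-schema", "1.0", function(work_dir) {
      jsonlite::write_json(list(candidates = list(list(rank = 5))),
                           file.path(work_dir, "out", "results.json"),
                           auto_unbox = TRUE)
    }))

  j1 <- enqueue_job(fx$store, "boom", uid, fx$user)
  j2 <- enqueue_job(fx$store, "no-results", uid, fx$user)
  j3 <- enqueue_job(fx$store, "bad-schema", uid, fx$user)
  j4 <- enqueue_job(fx$store, "toy-blob", uid, fx$user)

  r1 <- run_next_job(fx$store)
  expect_identical(r1$status, "failed")
  expect_match(r1$error, "detector exploded")
  log <- readLines(file.path(fx$store$path, "jobs", r1$job_id, "job.log"))
  expect_match(paste(log, collapse = "\n"), "detector exploded")

  r2 <- run_next_job(fx$store)
  expect_match(r2$error, "no out/results.json")
  r3 <- run_next_job(fx$store)
  expect_match(r3$error, "result schema")
  r4 <- run_next_job(fx$store)
  expect_identical(r4$status, "finished")
  expect_length(r4$results, 2)
})

test_that("command-runtime plug-ins run in the work directory", {
  fx <- job_store_fixture(1, seeds = 71)
  uid <- fx$fixtures[[1]]$entry$series_uid
  # a shell plug-in: proves cwd is the work dir and out/ is writable
  register_plugin(fx$store, plugin_manifest(
    "sh-plugin", "1.0",
    list(type = "command", command = "sh",
         args = c("-c",
                  shQuote(paste0(
                    "test -f series/0/volume.mhd && ",
                    "printf \'{\"candidates\": [], \"displays\": []}\' ",
                    "> out/results.json"))))))
  register_plugin(fx$store, plugin_manifest(
    "sh-fail", "1.0",
    list(type = "command", command = "sh", args = c("-c", "'exit 3'"))))

  j1 <- enqueue_job(fx$store, "sh-plugin", uid, fx$user)
  r1 <- run_next_job(fx$store)
  expect_identical(r1$status, "finished")
  expect_length(r1$results, 0)

  j2 <- enqueue_job(fx$store, "sh-fail", uid, fx$user)
  r2 <- run_next_job(fx$store)
  expect_identical(r2$status, "failed")
  expect_match(r2$error, "exited with status 3")
})
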