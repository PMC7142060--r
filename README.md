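# radcad

A headless R toolkit for developing and validating computer-assisted
detection/diagnosis (CAD) software against clinical imaging data. It is
aimed at researchers who need the *infrastructure* around a CAD algorithm
— ingesting DICOM series, building gold-standard voxel annotations,
running detection plug-ins in a sandbox, and collecting radiologist
feedback — without a web stack: everything is a library call or a shell
command, so the whole workflow is scriptable and testable.

## What it implements

* **Volume I/O** — a reader for single-frame DICOM series (Explicit VR
  Little Endian, monochrome) that sorts slices by the projection of
  ImagePositionPatient onto the slice normal, derives the slice spacing
  from adjacent positions (non-uniform spacing is an error, never a
  silent resample), and applies the rescale slope/intercept; a bit-exact
  ITK MetaImage (`.mhd` + `.raw`) writer/reader; PHI anonymization driven
  by a plain-text tag list; and a deterministic synthetic-series
  generator that plants spherical lesions of known centre, radius and
  intensity over Gaussian background noise.
* **MPR engine** — one deterministic reconstruction kernel for
  orthogonal and oblique sections. Output pixel `(i, j)` samples patient
  space at exactly `o + i·u + j·v`; trilinear interpolation computes
  `Σ w_c · v_c` over the 8 neighbouring voxels with weights
  `w_c = Π_a (c_a ? f_a : 1 − f_a)` for the fractional index `f`;
  window/level maps stored values to 8-bit greys via
  `round(clamp((v − (L − W/2)) / W, 0, 1) · 255)`.
* **Annotation database** — projects with attribute schemas (a fixed
  subset of JSON Schema), cases with globally unique ids, voxel labels
  (sparse masks with tight bounding boxes, mm-radius spherical brush) and
  2D geometric labels, append-only revisions, SHA-256 content
  fingerprints with integrity warnings, and anonymized case
  export/import as MetaImage + JSON archives.
* **Plug-in harness** — a strictly sequential FIFO job manager. Each
  job's work directory holds, per series, `volume.mhd`/`volume.raw` and a
  plain-text `metadata.txt`; plug-ins never receive DICOM files and never
  see PHI. Results come back as `results.json` (ranked lesion candidates)
  and radiologist feedback is recorded per candidate as known TP /
  missed TP / FP / pending plus false-negative location marks. A toy
  blob detector (threshold + 26-connected components) stands in for real
  CAD algorithms so the contract is exercisable end to end.
* **Store + CLI** — a JSON-document store with atomic writes and
  domain-based access control, and a `radcad` command-line tool
  (`inst/cli/radcad`) covering import, annotation, jobs and feedback.

## Worked example

```r
library(radcad)

store <- cad_store(tempfile("store"))
user  <- user_context("alice", domains = "trial",
                      roles = c("operator", "annotator"))

# a 32 x 32 x 16 series with two planted 400-intensity lesions
spec <- synthetic_spec(c(32, 32, 16), background_level = 50, noise_sd = 0,
                       lesions = list(
                         list(center = c(10, 10, 8), radius_mm = 3, intensity = 400),
                         list(center = c(24, 20, 6), radius_mm = 2, intensity = 400)),
                       seed = 11)
s      <- generate_synthetic_series(spec)
loaded <- load_dicom_series(s$payloads)
entry  <- store_series(store, loaded$volume, loaded$metadata, "trial", user)

register_plugin(store, plugin_manifest("toy-blob", "1.0",
                                       toy_plugin_runtime(threshold = 200,
                                                          min_voxels = 3)))
enqueue_job(store, "toy-blob", entry$series_uid, user)
job <- run_next_job(store)
job$status
#> [1] "finished"
for (c in job$results) cat("rank", c$rank, "at", unlist(c$location_voxel), "\n")
#> rank 1 at 10 10 8
#> rank 2 at 24 20 6

record_feedback(store, job$job_id,
                feedback_entry("bob", list(`1` = "known_TP", `2` = "FP"),
                               false_negatives = list(c(5, 5, 5))))
summarize_feedback(list_jobs(store))
#>   plugin_id known_TP missed_TP FP pending fn_marks entries
#> 1  toy-blob        1         0  1       0        1       1
```

Both planted lesions come back at exactly their planted centres (rank 1
is the larger component), and the feedback table counts one known TP,
one FP and one false-negative mark from one entry.

The same flow from a shell:

```sh
inst/cli/radcad synth generate --spec spec.json --seed 11 --out /tmp/dcm
inst/cli/radcad import /tmp/dcm --domain trial --store /tmp/store \
    --user alice --domains trial --roles operator
inst/cli/radcad job enqueue --series <uid> --store /tmp/store ...
```

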