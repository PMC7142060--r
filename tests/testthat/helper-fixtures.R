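# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing binary ships with the tests.

random_volume <- function(dims = c(8, 8, 8), value_type = "int16",
                          spacing = NULL, origin = NULL) {
  rng <- radcad:::value_type_range(value_type)
  lo <- max(rng[1], -1000)
  hi <- min(rng[2], 1000)
  data <- array(as.numeric(sample(lo:hi, prod(dims), replace = TRUE)),
                dim = dims)
  cad_volume(data,
             spacing = if (is.null(spacing)) runif(3, 0.4, 3) else spacing,
             origin = if (is.null(origin)) runif(3, -50, 50) else origin,
             value_type = value_type)
}

# independent per-pixel trilinear resampler: explicit loops, no shared
# code with oblique_section beyond the geometry constructors
brute_force_section <- function(volume, spec) {
  w <- spec$out_size[1]
  h <- spec$out_size[2]
  d <- volume$dims
  fill <- if (is.null(spec$fill_value)) min(volume$data) else spec$fill_value
  out <- matrix(0, w, h)
  for (i in 0:(w - 1)) {
    for (j in 0:(h - 1)) {
      p <- spec$origin + i * spec$u_axis + j * spec$v_axis
      x <- mm_to_voxel(volume, p)
      if (spec$interpolation == "nearest") {
        xi <- floor(x + 0.5)
        out[i + 1, j + 1] <- if (all(xi >= 0) && all(xi <= d - 1)) {
          volume$data[xi[1] + 1, xi[2] + 1, xi[3] + 1]
        } else fill
      } else {
        x0 <- floor(x)
        f <- x - x0
        acc <- 0
        bad <- FALSE
        for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
          wt <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
          ci <- x0 + c(cx, cy, cz)
          if (all(ci >= 0) && all(ci <= d - 1)) {
            acc <- acc + wt * volume$data[ci[1] + 1, ci[2] + 1, ci[3] + 1]
          } else if (wt > 0) bad <- TRUE
        }
        out[i + 1, j + 1] <- if (bad) fill else acc
      }
    }
  }
  out
}

# a random oblique plane whose samples stay loosely near the volume
random_section_spec <- function(volume, out_size = c(6, 5),
                                interpolation = "trilinear") {
  ctr <- voxel_to_mm(volume, (volume$dims - 1) / 2)
  a <- rnorm(3)
  b <- rnorm(3)
  b <- b - sum(a * b) / sum(a * a) * a      # orthogonalize for a sane plane
  u <- a / sqrt(sum(a^2)) * runif(1, 0.3, 1.5)
  v <- b / sqrt(sum(b^2)) * runif(1, 0.3, 1.5)
  org <- ctr - (out_size[1] / 2) * u - (out_size[2] / 2) * v +
    rnorm(3, sd = 1)
  section_spec(org, u, v, out_size, interpolation,
               fill_value = sample(c(list(NULL), list(-123)), 1)[[1]])
}

# non-overlapping lesion slots on a coarse lattice: spheres of radius
# <= 3.5 mm on a 1 mm grid can never touch across slots 12 voxels apart
lesion_slots <- function() {
  as.matrix(expand.grid(x = c(8, 20, 32), y = c(8, 20, 32), z = c(6, 18)))
}

planted_spec <- function(k, seed, noise_sd = 0) {
  set.seed(seed)
  slots <- lesion_slots()
  pick <- if (k > 0) slots[sample(nrow(slots), k), , drop = FALSE] else
    slots[integer(0), , drop = FALSE]
  lesions <- lapply(seq_len(k), function(i) {
    list(center = as.numeric(pick[i, ]),
         radius_mm = runif(1, 2, 3.5), intensity = 400)
  })
  synthetic_spec(c(40, 40, 24), spacing = c(1, 1, 1),
                 background_level = 50, noise_sd = noise_sd,
                 lesions = lesions, seed = seed)
}

operator_user <- function(domains = "trial") {
  user_context("op", domains = domains, roles = c("operator", "annotator"))
}

# store one synthetic series and return everything downstream tests need
stored_series_fixture <- function(store, spec, domain = "trial",
                                  user = operator_user()) {
  s <- generate_synthetic_series(spec)
  loaded <- load_dicom_series(s$payloads)
  entry <- store_series(store, loaded$volume, loaded$metadata, domain, user)
  list(series = s, volume = loaded$volume, metadata = loaded$metadata,
       entry = entry)
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE)
}

has_dicom_magic <- function(path) {
  if (file.size(path) < 132) return(FALSE)
  bytes <- readBin(path, "raw", n = 132)
  identical(bytes[129:132], charToRaw("DICM"))
}

nodule_project <- function() {
  cad_project(
    "lung nodule db",
    case_attribute_schema = list(
      type = "object",
      properties = list(
        status = list(type = "string",
                      enum = list("screening", "follow-up", "resolved")),
        nodule_count = list(type = "integer", minimum = 0)
      ),
      required = list("status")
    ),
    label_attribute_schema = list(
      type = "object",
      properties = list(
        size = list(type = "number", minimum = 0),
        diameter = list(type = "number", minimum = 0)
      ),
      required = list("size", "diameter")
    )
  )
}
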