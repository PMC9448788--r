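## On-disk ASL-BIDS layout: NIfTI images, JSON sidecars, the aslcontext TSV,
## dataset_description.json and README. Images are written fully scaled as
## 64-bit float with scl slope/intercept 1/0, so a write->read round trip is
## bit-identical and no latent scale factor survives conversion.

BIDS_VERSION <- "1.6.0"

#' Parse an `_aslcontext.tsv` document
#'
#' The file is a single-column TSV whose header line must be exactly
#' `volume_type`, followed by one volume-type token per line in acquisition
#' order. Tokens are case-sensitive lowercase.
#'
#' @param tsv_text The file contents as a single string or character vector
#'   of lines.
#' @return An [asl_context()].
#' @export
parse_aslcontext <- function(tsv_text) {
  lines <- if (length(tsv_text) == 1L) strsplit(tsv_text, "\r?\n")[[1]] else tsv_text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    asl_abort("malformed_tsv", "empty aslcontext")
  if (!identical(trimws(lines[1L]), "volume_type"))
    asl_abort("malformed_tsv", sprintf(
      "aslcontext header must be 'volume_type', got '%s'", lines[1L]))
  body <- trimws(lines[-1L])
  if (length(body) == 0L)
    asl_abort("malformed_tsv", "aslcontext has a header but no volume rows")
  bad <- setdiff(unique(body), VOLUME_TYPES)
  if (length(bad))
    asl_abort("malformed_tsv", sprintf(
      "unknown volume_type token(s): %s", paste(bad, collapse = ", ")))
  asl_context(body)
}

render_aslcontext <- function(context) {
  paste0(paste(c("volume_type", unclass(context)), collapse = "\n"), "\n")
}

# Normalise a value parsed from JSON (simplifyVector = FALSE): JSON arrays
# arrive as lists and are flattened to atomic vectors when homogeneous;
# scalars stay length-1 vectors.
normalise_json_value <- function(x) {
  if (!is.list(x)) return(x)
  flat <- lapply(x, normalise_json_value)
  if (all(vapply(flat, function(v) is.atomic(v) && length(v) == 1L, logical(1)))) {
    types <- vapply(flat, function(v) class(v)[1L], character(1))
    if (length(unique(types)) == 1L ||
        all(types %in% c("integer", "numeric")))
      return(unlist(flat, use.names = FALSE))
  }
  flat
}

#' Parse a JSON sidecar
#'
#' Values of registry-known fields are type-checked against their declared
#' value kind; a mismatch raises `type_mismatch` naming the field. Unknown
#' keys pass through. Numbers in scientific notation are accepted (standard
#' JSON).
#'
#' @param json_text Sidecar contents as a string.
#' @param role `"asl"`, `"m0scan"` or `"fieldmap"`.
#' @param registry Field registry used for type checking.
#' @return An [sidecar_metadata()] object.
#' @export
parse_sidecar <- function(json_text, role, registry = build_field_registry()) {
  parsed <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) asl_abort("malformed_json",
                                  sprintf("invalid JSON: %s", conditionMessage(e))))
  if (!is.list(parsed) || (length(parsed) && is.null(names(parsed))))
    asl_abort("malformed_json", "sidecar must be a JSON object")
  entries <- lapply(parsed, normalise_json_value)
  sidecar_metadata(role, entries, registry = registry)
}

render_sidecar <- function(sidecar) {
  if (length(sidecar$entries) == 0L) return("{}\n")
  paste0(jsonlite::toJSON(sidecar$entries, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE), "\n")
}

## NIfTI helpers ------------------------------------------------------------

write_nifti_series <- function(series, path) {
  vox <- series$voxels
  attr(vox, "pixdim") <- c(series$voxel_size_mm,
                           if (length(dim(vox)) == 4L) 1)
  img <- RNifti::asNifti(vox, datatype = "double")
  RNifti::writeNifti(img, path)
}

read_nifti_series <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  image_series(vox, voxel_size_mm = RNifti::pixdim(img)[1:3])
}

# Minimal 8x8 grayscale JPEG used as the anonymised labeling-plane
# screenshot placeholder written by the synthesizer.
labeling_screenshot_bytes <- function() {
  as.raw(strtoi(c(
    "ff","d8","ff","e0","00","10","4a","46","49","46","00","01","01","00",
    "00","01","00","01","00","00","ff","db","00","43","00","1b","12","14",
    "17","14","11","1b","17","16","17","1e","1c","1b","20","28","42","2b",
    "28","25","25","28","51","3a","3d","30","42","60","55","65","64","5f",
    "55","5d","5b","6a","78","99","81","6a","71","90","73","5b","5d","85",
    "b5","86","90","9e","a3","ab","ad","ab","67","80","bc","c9","ba","a6",
    "c7","99","a8","ab","a4","ff","c0","00","0b","08","00","08","00","08",
    "01","01","11","00","ff","c4","00","1f","00","00","01","05","01","01",
    "01","01","01","01","00","00","00","00","00","00","00","00","01","02",
    "03","04","05","06","07","08","09","0a","0b","ff","c4","00","b5","10",
    "00","02","01","03","03","02","04","03","05","05","04","04","00","00",
    "01","7d","01","02","03","00","04","11","05","12","21","31","41","06",
    "13","51","61","07","22","71","14","32","81","91","a1","08","23","42",
    "b1","c1","15","52","d1","f0","24","33","62","72","82","09","0a","16",
    "17","18","19","1a","25","26","27","28","29","2a","34","35","36","37",
    "38","39","3a","43","44","45","46","47","48","49","4a","53","54","55",
    "56","57","58","59","5a","63","64","65","66","67","68","69","6a","73",
    "74","75","76","77","78","79","7a","83","84","85","86","87","88","89",
    "8a","92","93","94","95","96","97","98","99","9a","a2","a3","a4","a5",
    "a6","a7","a8","a9","aa","b2","b3","b4","b5","b6","b7","b8","b9","ba",
    "c2","c3","c4","c5","c6","c7","c8","c9","ca","d2","d3","d4","d5","d6",
    "d7","d8","d9","da","e1","e2","e3","e4","e5","e6","e7","e8","e9","ea",
    "f1","f2","f3","f4","f5","f6","f7","f8","f9","fa","ff","da","00","08",
    "01","01","00","00","3f","00","2b","ff","d9"), 16L))
}

## Dataset writer/reader ----------------------------------------------------

#' Write an ASL dataset as a BIDS tree
#'
#' Emits `dataset_description.json`, `README`, and the subject's `perf/` (and
#' `fmap/`) contents. JSON is written UTF-8 with the sidecar's own stable key
#' order and full numeric precision, the aslcontext TSV with the single
#' header `volume_type` and LF line endings. `read_asl_dataset()` applied to
#' the result reproduces the dataset (images bit-identical, sidecars
#' key-equal, context order-equal).
#'
#' @param dataset An [asl_dataset()].
#' @param root Directory to create the tree under.
#' @param name Dataset name for `dataset_description.json`.
#' @return Character vector of written paths relative to `root` (invisibly).
#' @export
write_asl_dataset <- function(dataset, root, name = "aslbids synthetic dataset") {
  stopifnot(inherits(dataset, "asl_dataset"))
  sub <- paste0("sub-", dataset$subject)
  perf <- file.path(root, sub, "perf")
  ok <- dir.create(perf, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(perf))
    asl_abort("io_failure", sprintf("cannot create '%s'", perf))
  written <- character()
  emit <- function(rel, writer) {
    full <- file.path(root, rel)
    dir.create(dirname(full), recursive = TRUE, showWarnings = FALSE)
    writer(full)
    written <<- c(written, rel)
  }

  desc <- list(Name = name, BIDSVersion = BIDS_VERSION, DatasetType = "raw",
               GeneratedBy = list(list(Name = "aslbids",
                                       Version = as.character(utils::packageVersion("aslbids")))))
  emit("dataset_description.json", function(f)
    writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = TRUE), f,
               useBytes = TRUE))
  if (dataset$readme_present)
    emit("README", function(f) writeLines(c(
      name,
      "",
      "Synthetic arterial spin labeling dataset in ASL-BIDS layout.",
      "All intensity scale factors were applied at conversion; images store",
      "fully scaled floating-point values in acquisition order.",
      if (!is.null(sidecar_get(dataset$asl_sidecar, "M0Estimate"))) c(
        "",
        "M0Estimate origin: synthetic equilibrium-magnetization scalar taken",
        "from the generator's ground-truth phantom (flat within the brain)."
      )), f))

  p <- dataset_paths(dataset)
  emit(p$asl_image, function(f) write_nifti_series(dataset$asl_series, f))
  emit(p$asl_sidecar, function(f)
    cat(render_sidecar(dataset$asl_sidecar), file = f))
  emit(p$context, function(f) cat(render_aslcontext(dataset$context), file = f))
  if (!is.null(dataset$m0_series)) {
    emit(p$m0_image, function(f) write_nifti_series(dataset$m0_series, f))
    emit(p$m0_sidecar, function(f)
      cat(render_sidecar(dataset$m0_sidecar), file = f))
  }
  if (dataset$labeling_screenshot_present)
    emit(p$screenshot, function(f)
      writeBin(labeling_screenshot_bytes(), f))
  for (i in seq_along(dataset$fieldmap_entries)) {
    fe <- dataset$fieldmap_entries[[i]]
    emit(p$fmap_images[i], function(f) write_nifti_series(fe$series, f))
    emit(p$fmap_sidecars[i], function(f) cat(render_sidecar(fe$sidecar), file = f))
  }
  invisible(written)
}

read_text_file <- function(path) {
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

#' Read one subject of an ASL-BIDS tree
#'
#' Locates the single `_asl` run under `sub-<subject>/perf/` with its sidecar
#' and `_aslcontext.tsv`, plus the optional separate m0scan, PEPolar fieldmap
#' entries under `fmap/`, and the labeling screenshot. Image data are
#' returned as floating point exactly as stored: scaling happened at
#' conversion, never at read time. Exactly one ASL run per subject is
#' supported; multiple runs raise `ambiguous_layout`.
#'
#' @param root Dataset root (must contain `dataset_description.json`).
#' @param subject Subject label without the `sub-` prefix; defaults to the
#'   single `sub-*` directory present.
#' @param registry Field registry used for sidecar type checking.
#' @return An [asl_dataset()].
#' @export
read_asl_dataset <- function(root, subject = NULL,
                             registry = build_field_registry()) {
  if (!dir.exists(root))
    asl_abort("missing_file", sprintf("no such directory: '%s'", root))
  if (!file.exists(file.path(root, "dataset_description.json")))
    asl_abort("missing_file", "dataset_description.json not found at root")
  if (is.null(subject)) {
    subs <- basename(Filter(dir.exists,
                            list.files(root, pattern = "^sub-", full.names = TRUE)))
    if (length(subs) == 0L) asl_abort("missing_file", "no sub-* directory found")
    if (length(subs) > 1L)
      asl_abort("ambiguous_layout", "multiple subjects; pass `subject` explicitly")
    subject <- sub("^sub-", "", subs)
  }
  sub <- paste0("sub-", subject)
  perf <- file.path(root, sub, "perf")
  if (!dir.exists(perf))
    asl_abort("missing_file", sprintf("%s/perf/ not found", sub))
  perf_files <- list.files(perf)

  asl_imgs <- grep("_asl\\.nii(\\.gz)?$", perf_files, value = TRUE)
  if (length(asl_imgs) == 0L)
    asl_abort("missing_file", "no _asl image in perf/")
  if (length(asl_imgs) > 1L)
    asl_abort("ambiguous_layout",
              "multiple _asl images; one run per subject is supported")
  asl_stem <- sub("\\.nii(\\.gz)?$", "", asl_imgs)
  need <- function(fname, what) {
    f <- file.path(perf, fname)
    if (!file.exists(f)) asl_abort("missing_file", sprintf("%s not found", what))
    f
  }
  asl_json <- need(paste0(asl_stem, ".json"), "ASL sidecar")
  ctx_file <- need(paste0(sub, "_aslcontext.tsv"), "_aslcontext.tsv")

  asl_series <- read_nifti_series(file.path(perf, asl_imgs))
  asl_sidecar <- parse_sidecar(read_text_file(asl_json), "asl", registry)
  context <- parse_aslcontext(read_text_file(ctx_file))

  m0_series <- m0_sidecar <- NULL
  m0_imgs <- grep("_m0scan\\.nii(\\.gz)?$", perf_files, value = TRUE)
  if (length(m0_imgs) > 1L)
    asl_abort("ambiguous_layout", "multiple m0scan images in perf/")
  if (length(m0_imgs) == 1L) {
    m0_stem <- sub("\\.nii(\\.gz)?$", "", m0_imgs)
    m0_json <- need(paste0(m0_stem, ".json"), "m0scan sidecar")
    m0_series <- read_nifti_series(file.path(perf, m0_imgs))
    m0_sidecar <- parse_sidecar(read_text_file(m0_json), "m0scan", registry)
  }

  fieldmap_entries <- list()
  fmap <- file.path(root, sub, "fmap")
  if (dir.exists(fmap)) {
    fm_imgs <- grep("_m0scan\\.nii(\\.gz)?$", list.files(fmap), value = TRUE)
    for (img in fm_imgs) {
      ent <- parse_bids_name(img)
      json <- file.path(fmap, sub("\\.nii(\\.gz)?$", ".json", img))
      if (!file.exists(json))
        asl_abort("missing_file", sprintf("fieldmap sidecar for %s not found", img))
      fieldmap_entries[[length(fieldmap_entries) + 1L]] <- list(
        series = read_nifti_series(file.path(fmap, img)),
        sidecar = parse_sidecar(read_text_file(json), "fieldmap", registry),
        direction = ent$direction %||% "unknown")
    }
  }

  known <- c(asl_imgs, paste0(asl_stem, ".json"), paste0(sub, "_aslcontext.tsv"),
             m0_imgs, if (length(m0_imgs)) paste0(sub, "_m0scan.json"),
             paste0(sub, "_asllabeling.jpg"))
  extra <- setdiff(perf_files, known)
  asl_dataset(
    subject = subject,
    asl_series = asl_series, asl_sidecar = asl_sidecar, context = context,
    m0_series = m0_series, m0_sidecar = m0_sidecar,
    fieldmap_entries = fieldmap_entries,
    labeling_screenshot_present =
      file.exists(file.path(perf, paste0(sub, "_asllabeling.jpg"))),
    readme_present = file.exists(file.path(root, "README")),
    extra_files = if (length(extra)) file.path(sub, "perf", extra) else character()
  )
}
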