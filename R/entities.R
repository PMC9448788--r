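#' BIDS filename entities for the perf datatype
#'
#' Renders and parses filenames of the form
#' `sub-<label>[_ses-<label>][_acq-<label>][_dir-<label>][_run-<index>]_<suffix><ext>`.
#' Parsing then rendering is the identity on well-formed names.
#'
#' @param subject Subject label.
#' @param session,acquisition,direction Optional entity labels.
#' @param run Optional run index (integer).
#' @param suffix One of `asl`, `m0scan`, `aslcontext`, `asllabeling`.
#' @param extension One of `.nii`, `.nii.gz`, `.json`, `.tsv`, `.jpg`.
#' @return `bids_entities()` returns a `bids_entities` list;
#'   `render_bids_name()` a filename string; `parse_bids_name()` a
#'   `bids_entities` list (error `malformed_name` if unparseable).
#' @export
bids_entities <- function(subject, session = NULL, acquisition = NULL,
                          direction = NULL, run = NULL,
                          suffix, extension) {
  ok_label <- function(x) is.null(x) ||
    (is.character(x) && length(x) == 1L && grepl("^[A-Za-z0-9]+$", x))
  if (!ok_label(subject) || is.null(subject) ||
      !ok_label(session) || !ok_label(acquisition) || !ok_label(direction))
    asl_abort("malformed_name", "entity labels must be alphanumeric")
  if (!suffix %in% c("asl", "m0scan", "aslcontext", "asllabeling"))
    asl_abort("malformed_name", sprintf("unknown suffix '%s'", suffix))
  if (!extension %in% c(".nii", ".nii.gz", ".json", ".tsv", ".jpg"))
    asl_abort("malformed_name", sprintf("unknown extension '%s'", extension))
  structure(list(subject = subject, session = session,
                 acquisition = acquisition, direction = direction,
                 run = if (is.null(run)) NULL else as.integer(run),
                 suffix = suffix, extension = extension),
            class = "bids_entities")
}

#' @rdname bids_entities
#' @param entities A `bids_entities` object.
#' @export
render_bids_name <- function(entities) {
  e <- entities
  parts <- paste0("sub-", e$subject)
  if (!is.null(e$session)) parts <- paste0(parts, "_ses-", e$session)
  if (!is.null(e$acquisition)) parts <- paste0(parts, "_acq-", e$acquisition)
  if (!is.null(e$direction)) parts <- paste0(parts, "_dir-", e$direction)
  if (!is.null(e$run)) parts <- paste0(parts, "_run-", e$run)
  paste0(parts, "_", e$suffix, e$extension)
}

#' @rdname bids_entities
#' @param name A filename (no directory components).
#' @export
parse_bids_name <- function(name) {
  rx <- paste0(
    "^sub-([A-Za-z0-9]+)",
    "(?:_ses-([A-Za-z0-9]+))?",
    "(?:_acq-([A-Za-z0-9]+))?",
    "(?:_dir-([A-Za-z0-9]+))?",
    "(?:_run-([0-9]+))?",
    "_(asl|m0scan|aslcontext|asllabeling)",
    "(\\.nii\\.gz|\\.nii|\\.json|\\.tsv|\\.jpg)$"
  )
  m <- regmatches(name, regexec(rx, name))[[1]]
  if (length(m) == 0L)
    asl_abort("malformed_name", sprintf("cannot parse BIDS name '%s'", name))
  g <- function(i) if (nzchar(m[i + 1L])) m[i + 1L] else NULL
  bids_entities(subject = g(1), session = g(2), acquisition = g(3),
                direction = g(4),
                run = if (is.null(g(5))) NULL else as.integer(g(5)),
                suffix = m[7L], extension = m[8L])
}
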