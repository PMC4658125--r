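#' Unattended batch operations
#'
#' The four stages of the unattended workflow — ingest, segment, save_crops,
#' export_metadata — each walk a directory of scans/documents, process every
#' candidate, and keep going on per-file failures (batch resilience). Each
#' returns a `batch_report` accounting for every candidate:
#' `processed + skipped + failed` equals the number of candidates.
#'
#' @name batch
NULL

RASTER_EXT <- "\\.(tiff?|jpe?g|png)$"

find_scans <- function(dir, recursive = FALSE) {
  sort(list.files(dir, pattern = RASTER_EXT, ignore.case = TRUE,
                  full.names = TRUE, recursive = recursive))
}

find_documents <- function(dir, recursive = FALSE) {
  sort(list.files(dir, pattern = "\\.inselect$", full.names = TRUE,
                  recursive = recursive))
}

new_batch_report <- function(status) {
  status <- as_tibble(status)
  structure(list(processed = sum(status$status == "processed"),
                 skipped = sum(status$status == "skipped"),
                 failed = status[status$status == "failed", c("path", "reason")],
                 status = status,
                 elapsed = attr(status, "elapsed") %||% NA_real_),
            class = "batch_report")
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> processed %d, skipped %d, failed %d (%.2f s)\n",
              x$processed, x$skipped, nrow(x$failed), x$elapsed))
  if (nrow(x$failed)) print(x$failed)
  invisible(x)
}

#' @export
tidy.batch_report <- function(x, ...) x$status

#' Map a batch report to a process exit code
#'
#' 0 when everything was processed or skipped, 2 on partial failure.
#' (Usage errors exit 1 in the command-line wrapper.)
#'
#' @param report A `batch_report`.
#' @return An integer exit code.
#' @export
batch_exit_code <- function(report) if (nrow(report$failed) > 0L) 2L else 0L

run_batch <- function(paths, fn, quiet = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  status <- map(paths, function(p) {
    res <- tryCatch(fn(p), error = function(e) {
      structure(conditionMessage(e), class = "batch_failure")
    })
    if (inherits(res, "batch_failure"))
      out <- tibble(path = p, status = "failed", reason = as.character(res))
    else
      out <- tibble(path = p, status = if (isTRUE(res)) "processed" else "skipped",
                    reason = NA_character_)
    if (!quiet)
      message(sprintf("[%s] %s%s", out$status, p,
                      if (is.na(out$reason)) "" else paste0(": ", out$reason)))
    out
  })
  status <- bind_rows(status)
  if (nrow(status) == 0L)
    status <- tibble(path = character(), status = character(), reason = character())
  attr(status, "elapsed") <- proc.time()[["elapsed"]] - t0
  new_batch_report(status)
}

#' @describeIn batch Create an empty document plus thumbnail for every
#'   recognized raster in `dir` that has none; existing documents are skipped
#'   unless `overwrite = TRUE`.
#' @param dir Directory of scans/documents.
#' @param template Optional `template_spec` (thumbnail width, template name).
#' @param width Thumbnail width override (flag beats template beats the
#'   4,096 px default).
#' @param overwrite Re-ingest scans that already have a document?
#' @param recursive Walk subdirectories?
#' @param quiet Suppress the one-line per-file status messages?
#' @export
batch_ingest <- function(dir, template = NULL, width = NULL, overwrite = FALSE,
                         recursive = FALSE, quiet = TRUE) {
  if (!dir.exists(dir)) stop_input(sprintf("directory not found: %s", dir))
  scans <- find_scans(dir, recursive)
  scans <- scans[!grepl("_thumbnail\\.jpg$", scans)]
  run_batch(scans, function(p) {
    if (file.exists(document_path(p)) && !overwrite) return(FALSE)
    ingest(p, template = template, width = width, overwrite = overwrite)
    TRUE
  }, quiet = quiet)
}

#' @describeIn batch Run automatic segmentation for every document that does
#'   not already contain bounding boxes (all documents with `force = TRUE`).
#' @param params A [seg_params] object.
#' @param force Re-segment documents that already have boxes?
#' @param segmenter Name of a registered segmentation algorithm.
#' @export
batch_segment <- function(dir, params = seg_params(), force = FALSE,
                          recursive = FALSE, segmenter = "edge", quiet = TRUE) {
  if (!dir.exists(dir)) stop_input(sprintf("directory not found: %s", dir))
  seg <- get_segmenter(segmenter)
  run_batch(find_documents(dir, recursive), function(p) {
    doc <- load_document(p)
    if (nrow(doc$boxes) > 0L && !force) return(FALSE)
    thumb <- load_image(doc$thumbnail_path)
    doc <- replace_boxes(doc, seg(thumb, params), force = force)
    save_document(doc, p)
    TRUE
  }, quiet = quiet)
}

#' @describeIn batch Write per-specimen crops from the full-resolution scan
#'   for every document; crops for each document land in
#'   `out_dir/<scan-stem>/`.
#' @param out_dir Root output directory for crops.
#' @param format Crop format, `"jpg"` or `"tiff"`.
#' @export
batch_save_crops <- function(dir, out_dir = file.path(dir, "crops"),
                             template = NULL, format = "jpg",
                             recursive = FALSE, quiet = TRUE) {
  if (!dir.exists(dir)) stop_input(sprintf("directory not found: %s", dir))
  run_batch(find_documents(dir, recursive), function(p) {
    doc <- load_document(p)
    stem <- tools::file_path_sans_ext(basename(p))
    export_crops(doc, template = template,
                 out_dir = file.path(out_dir, stem), format = format)
    TRUE
  }, quiet = quiet)
}

#' @describeIn batch Write one metadata CSV per document
#'   (`<scan-stem>.csv`, next to the document). With a template, rows failing
#'   validation are still written and flagged in a `valid` column; failures
#'   are reported as messages, never fatal.
#' @export
batch_export_metadata <- function(dir, template = NULL, recursive = FALSE,
                                  quiet = TRUE) {
  if (!dir.exists(dir)) stop_input(sprintf("directory not found: %s", dir))
  run_batch(find_documents(dir, recursive), function(p) {
    doc <- load_document(p)
    out <- csv_path_for(p)
    export_csv(doc, template = template, path = out,
               include_valid = !is.null(template))
    if (!is.null(template) && !quiet) {
      n_bad <- sum(!map_lgl(doc$boxes$fields, function(f) validate_box(f, template)$ok))
      if (n_bad > 0L)
        message(sprintf("validation: %d box(es) in %s fail the template", n_bad, p))
    }
    TRUE
  }, quiet = quiet)
}
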