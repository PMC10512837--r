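# Persistence helpers. Frame sequences, fields and masks are stored as RDS
# containers; key points and result tables as CSV; configs and summaries as
# JSON.

#' Write / read a simulated RF sequence
#'
#' Stores the frame list, acquisition metadata, motion-model description
#' and seed in one RDS container. The analytic ground-truth closures are
#' reconstructed from the stored motion model on read.
#'
#' @param sequence The list returned by [generate_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly (write) or the restored sequence (read).
#' @export
write_sequence <- function(sequence, path) {
  obj <- list(frames = sequence$frames,
              model = sequence$truth$model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  obj <- readRDS(path)
  n_pairs <- obj$model$n_frames - 1L
  fld <- motion_field_fn(obj$model)
  truth <- structure(
    list(model = obj$model, n_frames = obj$model$n_frames,
         incremental = function(pair = 1L) fld,
         cumulative = function(n = n_pairs) {
           function(z, x) {
             d <- fld(z, x)
             list(d_axial_mm = d$d_axial_mm * n,
                  d_lateral_mm = d$d_lateral_mm * n)
           }
         }),
    class = "ground_truth")
  list(frames = obj$frames, truth = truth)
}

#' Write / read border key points as CSV
#'
#' Columns: `border` (endo/epi), `index`, `axial_mm`, `lateral_mm`.
#'
#' @param endo_keypoints,epi_keypoints Key-point data frames.
#' @param path CSV path.
#' @return `path` invisibly (write); a list with `endo_keypoints` and
#'   `epi_keypoints` (read).
#' @export
write_keypoints_csv <- function(endo_keypoints, epi_keypoints, path) {
  endo <- as_points_df(endo_keypoints, "endo_keypoints")
  epi <- as_points_df(epi_keypoints, "epi_keypoints")
  df <- rbind(data.frame(border = "endo", index = seq_len(nrow(endo)), endo),
              data.frame(border = "epi", index = seq_len(nrow(epi)), epi))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path) {
  df <- read.csv(path)
  split_one <- function(role) {
    d <- df[df$border == role, , drop = FALSE]
    d <- d[order(d$index), c("axial_mm", "lateral_mm")]
    rownames(d) <- NULL
    d
  }
  list(endo_keypoints = split_one("endo"), epi_keypoints = split_one("epi"))
}

#' Write a quality report as CSV plus JSON summary
#'
#' @param report A `quality_report` from [overlap_sweep()].
#' @param csv_path CSV of the per-overlap records.
#' @param json_path Optional JSON with the selected overlap.
#' @return `csv_path` invisibly.
#' @export
write_quality_report <- function(report, csv_path, json_path = NULL) {
  write.csv(report$records, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(selected_overlap = report$selected_overlap),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
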