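#' Default adjacency of the AHA 17-segment polar map
#'
#' The left ventricle is divided into basal (1-6), mid (7-12) and apical
#' (13-16) rings plus the apex (17). Neighbours are: circumferential within
#' each ring (with ring closure 6-1, 12-7, 16-13), radial between rings
#' aligned by sector (1-7 .. 6-12; the 6-sector mid ring maps onto the
#' 4-sector apical ring as 7-13, 8-13, 8-14, 9-14, 10-15, 11-15, 11-16,
#' 12-16), and the apex touching all four apical segments. The published rule
#' does not enumerate its adjacency, so this table is a documented
#' convention and fully replaceable via [perfusion_rule_config()].
#'
#' @return symmetric, irreflexive 17x17 logical matrix.
#' @export
aha17_adjacency <- function() {
  edges <- aha17_edges()
  A <- matrix(FALSE, 17L, 17L)
  A[edges] <- TRUE
  A[edges[, c(2L, 1L)]] <- TRUE
  dimnames(A) <- list(1:17, 1:17)
  A
}

aha17_edges <- function() {
  ring <- function(segs) cbind(segs, c(segs[-1L], segs[1L]))
  rbind(
    ring(1:6),                    # basal ring
    ring(7:12),                   # mid ring
    ring(13:16),                  # apical ring
    cbind(1:6, 7:12),             # basal-mid radial
    matrix(c(7, 13, 8, 13, 8, 14, 9, 14, 10, 15,
             11, 15, 11, 16, 12, 16), ncol = 2L, byrow = TRUE),
    cbind(17L, 13:16)             # apex cap
  )
}

#' Build an adjacency matrix from an explicit edge list
#'
#' @param edges two-column matrix or data frame of segment pairs in
#'   `1..17`, or a JSON file path holding an array of two-element arrays.
#' @return symmetric, irreflexive 17x17 logical matrix.
#' @export
adjacency_from_edges <- function(edges) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- do.call(rbind, lapply(jsonlite::read_json(edges),
                                   function(e) as.integer(unlist(e))))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || any(edges < 1L) || any(edges > 17L) ||
      any(edges[, 1L] == edges[, 2L]))
    stop_field("edges", "must be pairs of distinct segments in 1..17")
  A <- matrix(FALSE, 17L, 17L)
  A[edges] <- TRUE
  A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  dimnames(A) <- list(1:17, 1:17)
  A
}

#' Configuration of the PET perfusion abnormality rule
#'
#' Stress perfusion is abnormal when hyperaemic myocardial blood flow (MBF)
#' is at or below `threshold` in at least two adjacent segments, the basal
#' septum excluded.
#'
#' @param threshold MBF threshold, mL/min/g (default 2.30; the comparison is
#'   `<=`).
#' @param excluded_segments segments ignored by the rule; default `c(2, 3)`,
#'   the basal anteroseptal and basal inferoseptal segments taken as the
#'   basal septum.
#' @param adjacency symmetric irreflexive 17x17 logical matrix; default
#'   [aha17_adjacency()].
#' @return object of class `perfusion_rule_config`.
#' @export
perfusion_rule_config <- function(threshold = 2.30,
                                  excluded_segments = c(2L, 3L),
                                  adjacency = aha17_adjacency()) {
  check_scalar_number(threshold, "threshold", lower = 0, open_lower = TRUE)
  excluded_segments <- as.integer(excluded_segments)
  if (length(excluded_segments) &&
      (any(excluded_segments < 1L) || any(excluded_segments > 17L)))
    stop_field("excluded_segments", "must be a subset of 1..17")
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == c(17L, 17L)))
    stop_field("adjacency", "must be 17x17")
  mode(adjacency) <- "logical"
  if (any(diag(adjacency)))
    stop_field("adjacency", "must be irreflexive")
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop_field("adjacency", "must be symmetric")
  structure(list(threshold = threshold,
                 excluded_segments = excluded_segments,
                 adjacency = adjacency),
            class = "perfusion_rule_config")
}

#' Classify 17-segment stress perfusion as abnormal or normal
#'
#' @param mbf numeric vector of 17 hyperaemic MBF values (mL/min/g), indexed
#'   by AHA segment number; all values must be positive and finite.
#' @param config a [perfusion_rule_config()].
#' @return `TRUE` iff two distinct, adjacent, non-excluded segments both
#'   have MBF at or below the threshold.
#' @examples
#' mbf <- rep(3, 17); mbf[c(7, 13)] <- 2
#' classify_perfusion(mbf)  # TRUE: segments 7 and 13 are adjacent
#' @export
classify_perfusion <- function(mbf, config = perfusion_rule_config()) {
  if (!inherits(config, "perfusion_rule_config"))
    stop_field("config", "must be a perfusion_rule_config")
  if (!is.numeric(mbf) || length(mbf) != 17L)
    stop_field("mbf", "must hold exactly 17 segment values")
  if (any(!is.finite(mbf)) || any(mbf <= 0))
    stop_field("mbf", "values must be positive and finite")
  low <- mbf <= config$threshold
  low[config$excluded_segments] <- FALSE
  if (sum(low) < 2L) return(FALSE)
  any(config$adjacency[low, low, drop = FALSE])
}

#' Composite ischemic-CAD label
#'
#' Patients referred to PET carry the perfusion result; patients never
#' referred (obstructive stenosis excluded on clinical CTA reading) are
#' labelled non-ischemic by definition.
#'
#' @param pet_performed logical: was PET performed?
#' @param abnormal logical perfusion result; must be supplied exactly when
#'   `pet_performed` is `TRUE` (vectorized: use `NA` where PET was not
#'   performed).
#' @return logical ischemic-CAD label.
#' @export
assign_label <- function(pet_performed, abnormal = NULL) {
  pet_performed <- as.logical(pet_performed)
  if (is.null(abnormal)) abnormal <- rep(NA, length(pet_performed))
  abnormal <- as.logical(abnormal)
  if (length(abnormal) != length(pet_performed))
    stop_field("abnormal", "must match pet_performed in length")
  if (any(pet_performed & is.na(abnormal)))
    stop("perfusion result missing for a patient with PET performed",
         call. = FALSE)
  if (any(!pet_performed & !is.na(abnormal)))
    stop("perfusion result supplied for a patient without PET",
         call. = FALSE)
  ifelse(pet_performed, abnormal, FALSE)
}

#' Read per-patient segmental perfusion from CSV
#'
#' Expected header: `patient_id,seg1,...,seg17` (hyperaemic MBF values).
#'
#' @param path CSV file path.
#' @return data frame with `patient_id` and a 17-column numeric matrix
#'   column `mbf`.
#' @export
read_perfusion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", paste0("seg", 1:17))
  if (!all(need %in% names(df)))
    stop_field("perfusion csv", "header must be patient_id,seg1..seg17")
  mbf <- as.matrix(df[, paste0("seg", 1:17)])
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)
  out$mbf <- mbf
  out
}
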