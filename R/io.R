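COHORT_CSV_HEADER <- c("patient_id", "stenosis_pct", "pav_pct", "ncpv_pct",
                       "cpv_pct", "pet_performed", "ischemia")

#' Write a cohort to the interchange CSV schema
#'
#' Exact header `patient_id,stenosis_pct,pav_pct,ncpv_pct,cpv_pct,
#' pet_performed,ischemia`; booleans as 0/1, UTF-8, RFC 4180 quoting. The
#' simulation-only `latent_ischemia` column is deliberately not part of the
#' interchange schema.
#'
#' @param cohort data frame as returned by [generate_cohort()] (or any frame
#'   with the same columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(patient_id = as.character(cohort$patient_id),
                    stenosis_pct = cohort$stenosis,
                    pav_pct = cohort$pav,
                    ncpv_pct = cohort$ncpv,
                    cpv_pct = cohort$cpv,
                    pet_performed = as.integer(cohort$pet_performed),
                    ischemia = as.integer(cohort$ischemia))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from the interchange CSV schema
#'
#' @param path CSV file with the header written by [write_cohort_csv()].
#' @return data frame with columns `patient_id`, `stenosis`, `pav`, `ncpv`,
#'   `cpv`, `pet_performed`, `ischemia`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!identical(names(df), COHORT_CSV_HEADER))
    stop_field("cohort csv",
               paste("header must be exactly:",
                     paste(COHORT_CSV_HEADER, collapse = ",")))
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stenosis = as.numeric(df$stenosis_pct),
                    pav = as.numeric(df$pav_pct),
                    ncpv = as.numeric(df$ncpv_pct),
                    cpv = as.numeric(df$cpv_pct),
                    pet_performed = df$pet_performed != 0L,
                    ischemia = df$ischemia != 0L,
                    stringsAsFactors = FALSE)
  bad <- which(out$stenosis < 0 | out$stenosis > 100 |
                 out$pav < 0 | out$pav > 100)
  if (length(bad))
    stop_field("cohort csv",
               sprintf("stenosis/pav out of [0,100] at row %d", bad[1L]))
  if (any(out$ischemia & !out$pet_performed))
    stop_field("cohort csv",
               "composite label violated: ischemia without pet_performed")
  out
}
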