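#' Packaged confusion-matrix fixtures for the three published models
#'
#' Loads the three 2x2 patient-frequency tables of the registry analysis:
#' Model 1 (binary stenosis >= 50%), Model 2 (stenosis >= 50% gate + PAV >=
#' 16.8%) and Model 3 (staged 30-70% band + PAV >= 12.2%), each cross-
#' tabulated against the composite ischemic-CAD reference label in the same
#' 2145 patients (373 reference-positive, 1772 reference-negative).
#'
#' @param path JSON file with keys `model1`/`model2`/`model3`, each holding
#'   `tp`, `fp`, `fn`, `tn`. Defaults to the versioned file shipped with the
#'   package.
#' @return named list of three [confusion_matrix()] objects.
#' @examples
#' fx <- load_fixture_matrices()
#' sum(unlist(fx$model1))  # 2145
#' @export
load_fixture_matrices <- function(path = system.file("extdata",
                                                     "table_fixtures.json",
                                                     package = "stagedcad")) {
  if (!nzchar(path) || !file.exists(path))
    stop("fixture file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- c("model1", "model2", "model3")
  if (!all(models %in% names(raw)))
    stop("fixture file must contain keys model1, model2, model3",
         call. = FALSE)
  out <- lapply(raw[models], function(m)
    confusion_matrix(tp = m[["tp"]], fp = m[["fp"]],
                     fn = m[["fn"]], tn = m[["tn"]]))
  out
}
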