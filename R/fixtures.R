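# Transcribed in-study fixture tables: the matched primary/metastasis DSG2
# status cohort, the rapid-autopsy positivity counts, and the DSG2-by-stage
# contingency table reconstructed from the reported percentages (derivation
# documented in the fixture files under inst/extdata/).

#' Load the bundled patient fixture tables
#'
#' Returns the transcribed matched-cohort table (8 patients, paired
#' primary/metastasis DSG2 status plus metastasis site), the rapid-autopsy
#' positivity counts (6/6, 5/6, 2/5) and the 2x2 DSG2-by-stage contingency
#' table (rows: primary n=46, metastatic n=25; columns: DSG2+, DSG2-).
#'
#' @return object of class `vmq_fixtures` with elements
#'   `matched_cohort_table` (data.frame), `autopsy_counts` (data.frame) and
#'   `stage_contingency` (2x2 integer matrix).
#' @export
load_paper_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "vmquant")
    if (p == "") abort("fixture file %s not found; is vmquant installed?", f)
    p
  }
  matched <- utils::read.delim(path("table1_matched_cohort.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE)
  autopsy <- utils::read.delim(path("autopsy_counts.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE)
  cont <- utils::read.delim(path("stage_contingency.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE)
  stage <- as.matrix(cont[, c("dsg2_pos", "dsg2_neg")])
  storage.mode(stage) <- "integer"
  dimnames(stage) <- list(cont$cohort, c("dsg2_pos", "dsg2_neg"))
  structure(
    list(matched_cohort_table = matched, autopsy_counts = autopsy,
         stage_contingency = stage),
    class = "vmq_fixtures"
  )
}

#' @export
print.vmq_fixtures <- function(x, ...) {
  cat(sprintf("<vmq_fixtures> matched cohort: %d patients; autopsy: %d patients; stage table rows: %s\n",
              nrow(x$matched_cohort_table), nrow(x$autopsy_counts),
              paste(rownames(x$stage_contingency), collapse = ", ")))
  invisible(x)
}
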