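#' Load the bundled participant-characteristics table
#'
#' A per-decade summary of the study cohort the pipeline is designed for:
#' age-range rows with participant counts by sex and mean (s.d.) ACE-R
#' scores. Shipped as plain CSV under `inst/extdata`.
#'
#' @param path optional path to an alternative CSV with the same columns.
#' @return data.frame with columns `age_min`, `age_max`, `count`, `male`,
#'   `female`, `acer_total_mean`, `acer_total_sd`.
#' @export
load_participant_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "participant_characteristics.csv",
                        package = "icchub", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_min", "age_max", "count", "male", "female")
  if (!all(need %in% names(tab)))
    stop("participant table must contain columns: ", paste(need, collapse = ", "))
  tab
}

#' Participant counts from an age-range summary table
#'
#' Recomputes the total cohort size and the young-adult subgroup size (rows
#' whose age range lies entirely below `young_max_age`, default 40 years)
#' from the per-decade rows.
#'
#' @param table data.frame from [load_participant_table()].
#' @param young_max_age upper age bound (exclusive) of the young subgroup.
#' @return List with `total`, `young`, `male`, `female`.
#' @export
participant_counts <- function(table = load_participant_table(),
                               young_max_age = 40) {
  young <- table$age_max < young_max_age
  list(total = sum(table$count), young = sum(table$count[young]),
       male = sum(table$male), female = sum(table$female))
}
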