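#' Per-animal behavioral cohort table
#'
#' Long-format table with one row per (animal, endpoint[, within-level]):
#' columns `animal_id`, `genotype` (`"+/+"`, `"+/ls"`, `"+/-"`), `cre`
#' (`"-"`/`"+"`), `tmx` (`"-"`/`"+"`), `endpoint`, `value`, and optionally
#' `within` for repeated-measures designs (e.g. pre/post treatment or
#' wake/sleep).
#'
#' @param df a data frame with the columns above.
#' @return a `cohort_table` (a classed data frame).
#' @export
cohort_table <- function(df) {
  req <- c("animal_id", "genotype", "cre", "tmx", "endpoint", "value")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("cohort table needs columns ", paste(req, collapse = ", "))
  bad_g <- setdiff(unique(df$genotype), c("+/+", "+/ls", "+/-", NA))
  if (length(bad_g))
    stop("unknown genotype level(s): ", paste(bad_g, collapse = ", "))
  bad_c <- setdiff(unique(df$cre), c("-", "+", NA))
  if (length(bad_c))
    stop("unknown cre level(s): ", paste(bad_c, collapse = ", "))
  if (!is.numeric(df$value)) stop("`value` must be numeric")
  key_cols <- intersect(c("animal_id", "endpoint", "within"), names(df))
  if (anyDuplicated(df[, key_cols]))
    stop("duplicate (animal, endpoint",
         if ("within" %in% names(df)) ", within" else "", ") rows")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @rdname cohort_table
#' @param path CSV file path.
#' @export
write_cohort_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_table
#' @export
read_cohort_table <- function(path) {
  cohort_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# wide matrix animal x endpoint for one endpoint set, used by MANOVA
cohort_wide <- function(table, endpoints) {
  sub <- table[table$endpoint %in% endpoints, ]
  ids <- unique(sub$animal_id)
  mat <- matrix(NA_real_, length(ids), length(endpoints),
                dimnames = list(ids, endpoints))
  for (i in seq_len(nrow(sub)))
    mat[sub$animal_id[i], sub$endpoint[i]] <- sub$value[i]
  meta <- sub[!duplicated(sub$animal_id), c("animal_id", "genotype", "cre", "tmx")]
  meta <- meta[match(ids, meta$animal_id), ]
  list(values = mat, meta = meta)
}
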