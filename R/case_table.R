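#' Write a campaign case table
#'
#' One TSV row per case: identifiers, growth rate and fraction,
#' equitability, richness, SCFA fractions and per-species abundances.
#' Numeric columns are written with 12 significant digits so the table
#' round-trips losslessly at that precision.
#'
#' @param cases a `tradeoff_campaign` or its case table (data.frame).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_case_table <- function(cases, path) {
  df <- if (is.data.frame(cases)) cases else as.data.frame(cases)
  if (!nrow(df)) stop("empty case list", call. = FALSE)
  out <- df
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- ifelse(is.na(df[[cl]]), "NA",
                          sprintf("%.12g", df[[cl]]))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a campaign case table
#'
#' @param path TSV written by [write_case_table()].
#' @return data.frame with the same columns.
#' @export
read_case_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Dump a community solution to JSON
#'
#' @param solution a `community_solution`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_solution_json <- function(solution, path) {
  stopifnot(inherits(solution, "community_solution"))
  jsonlite::write_json(
    list(mu = solution$mu,
         abundances = as.list(solution$abundances),
         fluxes = as.list(solution$fluxes),
         exchange = as.list(solution$exchange),
         sum_p = solution$sum_p,
         status = solution$status),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a community solution dumped by [write_solution_json()]
#'
#' @param path JSON path.
#' @return A `community_solution`.
#' @export
read_solution_json <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(list(mu = obj$mu,
                 abundances = unlist(obj$abundances),
                 fluxes = unlist(obj$fluxes),
                 exchange = unlist(obj$exchange),
                 sum_p = obj$sum_p,
                 status = obj$status),
            class = "community_solution")
}
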