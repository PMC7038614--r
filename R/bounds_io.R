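#' Write / read flux-bound tables
#'
#' Bound tables are plain CSV files with columns `reaction_id`,
#' `lower_bound`, `upper_bound`. Reading applies the rows as overrides on a
#' model's bounds: reactions absent from the table keep their current
#' bounds, unknown reaction ids are an error, and the lb <= ub invariant is
#' re-checked after applying.
#'
#' @param model a [metabolic_model].
#' @param path CSV file.
#' @param bounds optional bound list (`lb`, `ub`) to write instead of the
#'   model bounds (e.g. an evolved individual's genome).
#' @return `write_bounds_table` the path; `read_bounds_table` a bound list
#'   with vectors `lb` and `ub` aligned to the model's reaction order.
#' @export
write_bounds_table <- function(model, path, bounds = NULL) {
  bl <- check_bounds(model, bounds)
  utils::write.csv(data.frame(reaction_id = model$reactions$id,
                              lower_bound = bl$lb, upper_bound = bl$ub),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bounds_table
#' @export
read_bounds_table <- function(model, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lower_bound", "upper_bound")
  if (!all(need %in% names(tab)))
    stop("bounds table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(tab$reaction_id, model$reactions$id)
  if (length(unknown))
    stop("bounds table names unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  j <- rxn_index(model, tab$reaction_id)
  lb[j] <- tab$lower_bound
  ub[j] <- tab$upper_bound
  bad <- which(lb > ub)
  if (length(bad))
    stop("override leaves lower bound above upper bound for reaction(s): ",
         paste(model$reactions$id[bad], collapse = ", "))
  list(lb = lb, ub = ub)
}
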