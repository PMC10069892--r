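#' Write a model to the tabular (TSV trio) dialect
#'
#' Emits `metabolites.tsv`, `reactions.tsv` and `objective.tsv` (UTF-8,
#' tab-separated, header row) into `dir`. Numeric fields are serialized with
#' 17 significant digits so that [read_tabular()] inverts the writer
#' bit-exactly. Stoichiometry is encoded per reaction as
#' `met:coeff;met:coeff`, EC numbers as a `;`-joined list.
#'
#' @param model a `metabolic_model`.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
write_tabular <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  num <- function(x) sprintf("%.17g", x)
  enc_st <- function(st) paste0(names(st), ":", num(unname(st)), collapse = ";")

  met <- data.frame(id = model$metabolites$id,
                    name = model$metabolites$name,
                    compartment = model$metabolites$compartment,
                    formula = ifelse(is.na(model$metabolites$formula), "",
                                     model$metabolites$formula),
                    is_boundary = model$metabolites$is_boundary,
                    stringsAsFactors = FALSE)
  rxn <- data.frame(id = model$reactions$id,
                    name = model$reactions$name,
                    lower_bound = num(model$reactions$lower_bound),
                    upper_bound = num(model$reactions$upper_bound),
                    ec_numbers = vapply(model$reactions$id, function(r) {
                      ec <- model$ec_numbers[[r]]
                      if (is.null(ec)) "" else paste(ec, collapse = ";")
                    }, ""),
                    stoichiometry = vapply(model$reactions$id, function(r)
                      enc_st(model$stoichiometry[[r]]), ""),
                    is_exchange = model$reactions$is_exchange,
                    is_transport = model$reactions$is_transport,
                    stringsAsFactors = FALSE)
  obj <- data.frame(reaction = names(model$objective),
                    weight = if (length(model$objective))
                      num(unname(model$objective)) else character(0),
                    stringsAsFactors = FALSE)

  paths <- file.path(dir, c("metabolites.tsv", "reactions.tsv", "objective.tsv"))
  wr <- function(df, path, header_comment = NULL) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header_comment)) writeLines(header_comment, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "")
  }
  wr(met, paths[1], paste0("# model: ", model$id))
  wr(rxn, paths[2])
  wr(obj, paths[3])
  invisible(paths)
}

#' Read a model from the tabular dialect
#'
#' Inverse of [write_tabular()].
#'
#' @param dir directory containing the TSV trio.
#' @return a `metabolic_model`.
#' @export
read_tabular <- function(dir) {
  paths <- file.path(dir, c("metabolites.tsv", "reactions.tsv", "objective.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing tabular files: ",
                            paste(missing, collapse = ", "))
  first <- readLines(paths[1], n = 1, encoding = "UTF-8")
  model_id <- if (startsWith(first, "# model: "))
    sub("^# model: ", "", first) else "model"
  rd <- function(path) {
    read.table(path, sep = "\t", header = TRUE, quote = "",
               comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character", encoding = "UTF-8")
  }
  met <- rd(paths[1])
  rxn <- rd(paths[2])
  obj <- rd(paths[3])

  metabolites <- data.frame(id = met$id, name = met$name,
                            compartment = met$compartment,
                            formula = ifelse(met$formula == "", NA_character_,
                                             met$formula),
                            is_boundary = as.logical(met$is_boundary),
                            stringsAsFactors = FALSE)
  stoich <- lapply(rxn$stoichiometry, function(s) {
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    st <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    names(st) <- vapply(parts, `[`, "", 1)
    st
  })
  names(stoich) <- rxn$id
  ecs <- lapply(rxn$ec_numbers, function(e)
    if (e == "") character(0) else strsplit(e, ";", fixed = TRUE)[[1]])
  names(ecs) <- rxn$id
  objective <- if (nrow(obj)) {
    stats::setNames(as.numeric(obj$weight), obj$reaction)
  } else numeric(0)

  metabolic_model(id = model_id,
                  metabolites = metabolites,
                  reactions = data.frame(id = rxn$id, name = rxn$name,
                                         lower_bound = as.numeric(rxn$lower_bound),
                                         upper_bound = as.numeric(rxn$upper_bound),
                                         stringsAsFactors = FALSE),
                  stoichiometry = stoich,
                  objective = objective,
                  ec_numbers = ecs)
}
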