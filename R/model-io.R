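#' Read a genome-scale metabolic model
#'
#' Reads SBML Level 3 (core) or BIGG-style JSON into a normalized
#' \linkS4class{MetabolicModel}. Reversibility is taken from the SBML
#' \code{reversible} attribute, or (BIGG dialect) set TRUE iff the lower flux
#' bound is negative. BIGG \code{gene_reaction_rule} strings are tokenized to
#' gene ids (OR semantics; boolean grammar is not evaluated). Boundary
#' reactions without both a substrate and a product side are dropped with a
#' message: they carry no metabolite-metabolite interaction.
#'
#' @param path model file
#' @param format "sbml" or "bigg_json"
#' @return a \linkS4class{MetabolicModel}
#' @export
readGenomeScaleModel <- function(path, format = c("sbml", "bigg_json")) {
  format <- match.arg(format)
  model <- if (format == "sbml") readSbmlModel(path) else readBiggJson(path)
  validObject(model)
  model
}

#' @rdname readGenomeScaleModel
#' @param model a \linkS4class{MetabolicModel}
#' @export
writeGenomeScaleModel <- function(model, path,
                                  format = c("sbml", "bigg_json")) {
  format <- match.arg(format)
  if (format == "sbml") writeSbmlModel(model, path)
  else writeBiggJson(model, path)
  invisible(path)
}

readBiggJson <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path), error = function(e)
    stop("unparseable BIGG JSON '", path, "': ", conditionMessage(e)))
  if (is.null(obj$metabolites) || is.null(obj$reactions))
    stop("BIGG JSON must contain 'metabolites' and 'reactions'")
  met <- data.frame(
    id = vapply(obj$metabolites, function(m) m$id, character(1)),
    name = vapply(obj$metabolites, function(m)
      if (is.null(m$name)) "" else m$name, character(1)),
    compartment = vapply(obj$metabolites, function(m)
      if (is.null(m$compartment)) "" else as.character(m$compartment),
      character(1)),
    stringsAsFactors = FALSE)
  reactions <- lapply(obj$reactions, function(rx) {
    st <- unlist(rx$metabolites)
    lb <- if (is.null(rx$lower_bound)) 0 else rx$lower_bound
    rule <- if (is.null(rx$gene_reaction_rule)) "" else rx$gene_reaction_rule
    genes <- tokenizeGeneRule(rule)
    list(id = rx$id, stoichiometry = st, reversible = lb < 0,
         genes = genes, source = "BIGG")
  })
  dropEmpty <- vapply(reactions, function(rx)
    !any(rx$stoichiometry < 0) || !any(rx$stoichiometry > 0), logical(1))
  if (any(dropEmpty))
    message("dropping ", sum(dropEmpty),
            " boundary/exchange reaction(s) without both substrates and ",
            "products")
  undeclared <- setdiff(
    unique(unlist(lapply(reactions[!dropEmpty],
                         function(rx) names(rx$stoichiometry)))), met$id)
  if (length(undeclared))
    stop("reactions reference undeclared metabolites: ",
         paste(undeclared, collapse = ", "))
  new("MetabolicModel", metabolites = met, reactions = reactions[!dropEmpty],
      organism = "")
}

writeBiggJson <- function(model, path) {
  obj <- list(
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(i) {
      m <- model@metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment)
    }),
    reactions = lapply(model@reactions, function(rx) {
      list(id = rx$id, metabolites = as.list(rx$stoichiometry),
           lower_bound = if (rx$reversible) -1000 else 0,
           upper_bound = 1000,
           gene_reaction_rule = paste(rx$genes, collapse = " or "))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# gene_reaction_rule -> gene id tokens (drops and/or and parentheses)
tokenizeGeneRule <- function(rule) {
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  unique(toks[!tolower(toks) %in% c("and", "or")])
}

#' Read an organism-specific model from KEGG flat-file records
#'
#' Offline-first: \code{source} is a directory containing a KEGG-style
#' reaction flat file (\code{reaction}; records with ENTRY, EQUATION and
#' ENZYME fields separated by \code{///}) and a two-column organism
#' enzyme-link table \code{<organism>_enzymes.tsv} (enzyme EC number, gene).
#' The model contains exactly the reactions whose enzymes occur in the
#' organism's enzyme list. EQUATION sides (separated by \code{<=>}) are
#' parsed into integer stoichiometries (default coefficient 1); malformed
#' EQUATION records are skipped with a warning and counted. Live retrieval
#' from the KEGG REST API is available behind \code{live = TRUE} and caches
#' into \code{source}.
#'
#' @param organism KEGG organism code (e.g. \code{"hsa"})
#' @param source directory with cached KEGG flat files
#' @param live allow network retrieval into the cache (default FALSE)
#' @return a \linkS4class{MetabolicModel}; KEGG reactions are treated as
#'   reversible (direction refinement comes from thermodynamics downstream)
#' @export
readKeggModel <- function(organism, source, live = FALSE) {
  reactionFile <- file.path(source, "reaction")
  enzymeFile <- file.path(source, paste0(organism, "_enzymes.tsv"))
  if (!file.exists(reactionFile) || !file.exists(enzymeFile)) {
    if (!live)
      stop("offline: KEGG cache incomplete in '", source,
           "' (need 'reaction' and '", basename(enzymeFile),
           "'); pass live = TRUE to retrieve and cache")
    dir.create(source, recursive = TRUE, showWarnings = FALSE)
    utils::download.file(paste0("https://rest.kegg.jp/link/", organism,
                                "/enzyme"), enzymeFile, quiet = TRUE)
    utils::download.file("https://rest.kegg.jp/list/reaction",
                         file.path(source, "reaction_list"), quiet = TRUE)
    stop("live KEGG retrieval fetched the enzyme table; full reaction ",
         "records must be mirrored into '", source, "/reaction' (one ",
         "ENTRY/EQUATION/ENZYME record per reaction, /// separated)")
  }
  enz <- utils::read.delim(enzymeFile, header = FALSE,
                           stringsAsFactors = FALSE)
  orgEnzymes <- unique(sub("^ec:", "", enz[[1]]))
  records <- strsplit(paste(readLines(reactionFile), collapse = "\n"),
                      "///", fixed = TRUE)[[1]]
  skipped <- 0L
  reactions <- list()
  compounds <- character(0)
  for (rec in records) {
    if (!grepl("ENTRY", rec)) next
    entry <- sub("^.*ENTRY\\s+(\\S+).*$", "\\1", rec)
    eq <- keggField(rec, "EQUATION")
    ez <- keggField(rec, "ENZYME")
    enzymes <- strsplit(trimws(ez), "\\s+")[[1]]
    if (!any(enzymes %in% orgEnzymes)) next
    st <- tryCatch(parseKeggEquation(eq), error = function(e) NULL)
    if (is.null(st)) {
      warning("skipping reaction ", entry, ": malformed EQUATION")
      skipped <- skipped + 1L
      next
    }
    compounds <- union(compounds, names(st))
    reactions[[length(reactions) + 1L]] <-
      list(id = entry, stoichiometry = st, reversible = TRUE,
           genes = enzymes, source = "KEGG")
  }
  met <- data.frame(id = sort(compounds), name = sort(compounds),
                    compartment = "", stringsAsFactors = FALSE)
  model <- new("MetabolicModel", metabolites = met, reactions = reactions,
               organism = organism)
  attr(model, "skipped") <- skipped
  validObject(model)
  model
}

keggField <- function(rec, field) {
  lines <- strsplit(rec, "\n")[[1]]
  hit <- grep(paste0("^", field, "\\s"), lines)
  if (!length(hit)) return("")
  # field content may continue on indented lines
  out <- sub(paste0("^", field, "\\s+"), "", lines[hit[1]])
  k <- hit[1] + 1L
  while (k <= length(lines) && grepl("^\\s{4,}", lines[k])) {
    out <- paste(out, trimws(lines[k]))
    k <- k + 1L
  }
  out
}

# "2 C00001 <=> 2 C00080 + C00007" -> named stoichiometry vector
parseKeggEquation <- function(eq) {
  sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("no <=> separator")
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (grepl("^\\+|\\+$|\\+\\s*\\+", side) || !nzchar(side))
      stop("dangling '+' or empty side")
    terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^(?:(\\d+)\\s+)?(C\\d{5})$", trimws(tm)))[[1]]
      if (length(m) == 0L) stop("unparseable term: ", tm)
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      out[m[3]] <- sign * coef
    }
    out
  }
  st <- c(parseSide(sides[1], -1), parseSide(sides[2], +1))
  if (any(names(st[st < 0]) %in% names(st[st > 0])))
    stop("substrates and products overlap")
  if (!any(st < 0) || !any(st > 0)) stop("one-sided equation")
  st
}

#' Read ModelSEED reaction thermodynamics
#'
#' TSV with reaction id, delta-G (kcal/mol) and direction columns. The
#' ModelSEED missing-value sentinel 10000000 yields an absent (NA) delta-G
#' and direction hint "unknown". Direction codes: \code{>} forward, \code{<}
#' reverse, \code{=} reversible.
#'
#' @param path TSV file
#' @param idColumn,deltaGColumn,directionColumn column names (ModelSEED
#'   defaults)
#' @return data.frame with columns reaction_id, delta_g, direction_hint
#' @export
readModelseedThermo <- function(path, idColumn = "id",
                                deltaGColumn = "deltag",
                                directionColumn = "direction") {
  empty <- data.frame(reaction_id = character(), delta_g = numeric(),
                      direction_hint = character(), stringsAsFactors = FALSE)
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || (nrow(df) == 0L && ncol(df) <= 1L)) return(empty)
  missing <- setdiff(c(idColumn, deltaGColumn, directionColumn), names(df))
  if (length(missing))
    stop("thermodynamics table lacks column(s) ",
         paste(missing, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "))
  dg <- suppressWarnings(as.numeric(df[[deltaGColumn]]))
  dg[!is.finite(dg) | abs(dg) >= 1e7] <- NA_real_
  hint <- c(">" = "forward", "<" = "reverse", "=" = "reversible")[
    as.character(df[[directionColumn]])]
  hint[is.na(hint)] <- "unknown"
  hint[is.na(dg) & hint == "unknown"] <- "unknown"
  data.frame(reaction_id = df[[idColumn]], delta_g = dg,
             direction_hint = unname(hint), stringsAsFactors = FALSE)
}

#' Trim reactions by gene expression (threshold rule)
#'
#' A reaction is discarded iff every one of its associated genes has
#' expression data and all those values fall below the threshold (OR
#' semantics over genes: one expressed gene keeps the reaction). Reactions
#' without gene associations, and genes absent from the expression table
#' ("no data"), never trigger removal. The input model is not modified.
#'
#' @param model a \linkS4class{MetabolicModel}
#' @param expression named numeric vector, gene -> expression
#' @param threshold finite activation threshold
#' @return trimmed \linkS4class{MetabolicModel}
#' @export
trimByExpression <- function(model, expression, threshold) {
  if (!is.finite(threshold) && !identical(threshold, -Inf))
    stop("threshold must be finite (or -Inf for no trimming)")
  missingGenes <- character(0)
  keep <- vapply(model@reactions, function(rx) {
    if (!length(rx$genes)) return(TRUE)
    known <- rx$genes %in% names(expression)
    if (any(!known))
      missingGenes <<- union(missingGenes, rx$genes[!known])
    if (any(!known)) return(TRUE)          # no data never triggers removal
    !all(expression[rx$genes] < threshold)
  }, logical(1))
  if (length(missingGenes))
    message(length(missingGenes),
            " gene(s) without expression data treated as 'no data'")
  out <- model
  out@reactions <- model@reactions[keep]
  out
}

#' Map dataset metabolite names to model ids
#'
#' Output order matches input order (this order defines the Jacobian row and
#' column order downstream). Names that are already model ids map to
#' themselves. All unmapped names are reported together in one error.
#'
#' @param names dataset metabolite names
#' @param mapping optional data.frame (dataset_name, model_id;
#'   '|'-separated for multi-mapping) as from
#'   \code{\link{readMetaboliteMapping}}
#' @param model a \linkS4class{MetabolicModel}
#' @return character vector of model metabolite ids, one per input name
#' @export
mapMetabolites <- function(names, mapping = NULL, model) {
  ids <- model@metabolites$id
  out <- character(length(names))
  unmapped <- character(0)
  for (k in seq_along(names)) {
    nm <- names[k]
    if (nm %in% ids) { out[k] <- nm; next }
    hit <- if (!is.null(mapping)) mapping$model_id[mapping$dataset_name == nm]
           else character(0)
    cands <- unlist(strsplit(hit, "|", fixed = TRUE))
    cands <- cands[cands %in% ids]
    if (!length(cands)) { unmapped <- c(unmapped, nm); next }
    if (length(cands) > 1L)
      warning("ambiguous mapping for '", nm, "' (",
              paste(cands, collapse = ", "), "); using first")
    out[k] <- cands[1]
  }
  if (length(unmapped))
    stop("unmapped metabolite name(s): ", paste(unmapped, collapse = ", "))
  out
}

#' @rdname mapMetabolites
#' @param path two-column TSV (dataset_name, model_id)
#' @export
readMetaboliteMapping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("mapping table needs two columns")
  names(df)[1:2] <- c("dataset_name", "model_id")
  df
}

#' Side (currency) metabolites excluded from pathway search
#'
#' Ubiquitous compounds (water, protons, cofactors) connect nearly every
#' reaction and would short-circuit pathway searches, so they are excluded
#' from the reaction graph. Matching is on compartment-stripped base ids.
#' The default list ships in \code{inst/extdata/side_metabolites.txt} and is
#' user-overridable.
#'
#' @return character vector of base ids
#' @export
defaultSideMetabolites <- function() {
  readSideMetabolites(system.file("extdata", "side_metabolites.txt",
                                  package = "covrecon"))
}

#' @rdname defaultSideMetabolites
#' @param path one base id per line; lines starting with '#' ignored
#' @export
readSideMetabolites <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
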