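## Model input/output: a plain TSV dialect and a minimal SBML Level 3 + fbc
## subset (species with boundary-condition flags, reactions with flux-bound
## parameters, one objective marking the biomass reaction).

#' Read a single-species model
#'
#' @param path file path.
#' @param format "tabular" or "sbml"; default guesses from the extension
#'   (.tsv/.txt vs .xml/.sbml).
#' @param species_id species identifier; default: file name without extension.
#' @param big_m replacement for infinite declared bounds (see
#'   [metabolic_model()]).
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "tabular", "sbml"),
                       species_id = NULL, big_m = .BIG_M_DEFAULT) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  switch(format,
         tabular = .read_tabular(path, species_id, big_m),
         sbml = .read_sbml(path, species_id, big_m))
}

#' Write a single-species model
#'
#' Inverse of [read_model()]: `read_model(write_model(m, p))` reproduces `m`
#' up to metabolite/reaction order.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format "tabular" or "sbml".
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tabular = .write_tabular(model, path),
         sbml = .write_sbml(model, path))
  invisible(path)
}

## ---- tabular dialect -------------------------------------------------------
## TSV columns: reaction_id  equation  reversible  lb  ub  tags
## equation syntax "2 A + B -> C"; external metabolites carry an "[e]" suffix;
## tags (comma separated): biomass, exchange, atp_maintenance.

.parse_side <- function(side) {
  side <- trimws(side)
  if (side == "") return(list())
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  lapply(terms, function(tm) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9.]+)\\s+(.*)$", tm))[[1]]
    if (length(m) == 3) list(coef = as.numeric(m[2]), met = m[3])
    else list(coef = 1, met = tm)
  })
}

.read_tabular <- function(path, species_id, big_m) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("reaction_id", "equation", "reversible", "lb", "ub")
  if (!all(need %in% names(tab))) {
    stop("tabular model ", path, ": missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (is.null(tab$tags)) tab$tags <- ""
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    eq <- strsplit(tab$equation[i], "->", fixed = TRUE)[[1]]
    if (length(eq) > 2) {
      stop("tabular model ", path, " line ", i + 1,
           ": malformed equation '", tab$equation[i], "'")
    }
    lhs <- .parse_side(eq[1])
    rhs <- if (length(eq) == 2) .parse_side(eq[2]) else list()
    list(lhs = lhs, rhs = rhs)
  })
  met_ids <- unique(unlist(lapply(entries, function(e)
    vapply(c(e$lhs, e$rhs), `[[`, "", "met"))))
  external <- grepl("\\[e\\]$", met_ids)
  S <- matrix(0, length(met_ids), nrow(tab),
              dimnames = list(met_ids, tab$reaction_id))
  for (i in seq_along(entries)) {
    for (tm in entries[[i]]$lhs) S[tm$met, i] <- S[tm$met, i] - tm$coef
    for (tm in entries[[i]]$rhs) S[tm$met, i] <- S[tm$met, i] + tm$coef
  }
  tags <- strsplit(tab$tags, "\\s*,\\s*")
  has_tag <- function(tag) vapply(tags, function(t) tag %in% t, TRUE)
  biomass <- tab$reaction_id[has_tag("biomass")]
  if (length(biomass) != 1L) {
    stop("tabular model ", path, ": need exactly one reaction tagged 'biomass'")
  }
  exch <- tab$reaction_id[has_tag("exchange")]
  atp <- tab$reaction_id[has_tag("atp_maintenance")]
  metabolic_model(
    species_id = species_id,
    mets = data.frame(id = met_ids, name = met_ids, external = external,
                      stringsAsFactors = FALSE),
    rxns = data.frame(id = tab$reaction_id,
                      reversible = tolower(tab$reversible) %in% c("true", "1", "yes"),
                      lb = as.numeric(tab$lb), ub = as.numeric(tab$ub),
                      stringsAsFactors = FALSE),
    S = S,
    biomass_id = biomass,
    exchange_ids = if (length(exch)) exch else NULL,
    atp_maintenance_id = if (length(atp)) atp else NULL,
    big_m = big_m)
}

.write_tabular <- function(model, path) {
  eqs <- vapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    fmt <- function(idx) paste(vapply(idx, function(i) {
      cf <- abs(col[i])
      if (abs(cf - 1) < 1e-12) rownames(model$S)[i]
      else paste(format(cf, scientific = FALSE, trim = TRUE), rownames(model$S)[i])
    }, ""), collapse = " + ")
    paste(fmt(which(col < 0)), "->", fmt(which(col > 0)))
  }, "")
  tags <- vapply(model$rxns$id, function(id) {
    t <- character(0)
    if (id == model$biomass_id) t <- c(t, "biomass")
    if (id %in% model$exchange_ids) t <- c(t, "exchange")
    if (!is.null(model$atp_maintenance_id) && id == model$atp_maintenance_id)
      t <- c(t, "atp_maintenance")
    paste(t, collapse = ",")
  }, "")
  out <- data.frame(reaction_id = model$rxns$id, equation = trimws(eqs),
                    reversible = tolower(model$rxns$reversible),
                    lb = model$rxns$lb, ub = model$rxns$ub, tags = tags,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---- SBML level 3 + fbc ----------------------------------------------------

.read_sbml <- function(path, species_id, big_m) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse failure in ", path, ": ", conditionMessage(e))
  })
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("SBML file ", path, ": no species elements")
  attr_of <- function(node, name, default = NA_character_) {
    a <- xml2::xml_attrs(node)
    hit <- which(names(a) == name | grepl(paste0(":", name, "$"), names(a)))
    if (length(hit)) a[[hit[1]]] else default
  }
  met_ids <- vapply(sp_nodes, attr_of, "", name = "id")
  met_names <- vapply(sp_nodes, attr_of, "", name = "name")
  met_names[is.na(met_names)] <- met_ids[is.na(met_names)]
  boundary <- vapply(sp_nodes, attr_of, "", name = "boundaryCondition")
  ## accept both the boundary-condition flag and an _e / [e] suffix convention
  external <- tolower(boundary) %in% "true" | grepl("(_e|\\[e\\])$", met_ids)

  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(attr_of(n, "value")), 0),
    vapply(par_nodes, attr_of, "", name = "id"))

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("SBML file ", path, ": no reactions")
  rxn_ids <- vapply(rx_nodes, attr_of, "", name = "id")
  rev <- tolower(vapply(rx_nodes, attr_of, "", name = "reversible")) %in% "true"
  bound_of <- function(node, which, default) {
    ref <- attr_of(node, which)
    if (!is.na(ref) && ref %in% names(par_val)) return(par_val[[ref]])
    v <- suppressWarnings(as.numeric(ref))
    if (!is.na(v)) v else default
  }
  lb <- vapply(seq_along(rx_nodes), function(i)
    bound_of(rx_nodes[[i]], "lowerFluxBound", if (rev[i]) -Inf else 0), 0)
  ub <- vapply(rx_nodes, bound_of, 0, which = "upperFluxBound", default = Inf)

  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (i in seq_along(rx_nodes)) {
    for (kind in c("listOfReactants", "listOfProducts")) {
      sgn <- if (kind == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx_nodes[[i]],
        sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", kind))
      for (ref in refs) {
        met <- attr_of(ref, "species")
        coef <- as.numeric(attr_of(ref, "stoichiometry", "1"))
        if (!met %in% met_ids) {
          stop("SBML file ", path, ": reaction ", rxn_ids[i],
               " references undeclared species ", met)
        }
        S[met, i] <- S[met, i] + sgn * coef
      }
    }
  }

  ## biomass reaction: the (single) fbc objective
  obj_refs <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  biomass <- unique(vapply(obj_refs, attr_of, "", name = "reaction"))
  if (length(biomass) != 1L || is.na(biomass)) {
    stop("SBML file ", path,
         ": no biomass reaction identifiable (need exactly one fbc objective)")
  }
  metabolic_model(
    species_id = species_id,
    mets = data.frame(id = met_ids, name = met_names, external = external,
                      stringsAsFactors = FALSE),
    rxns = data.frame(id = rxn_ids, reversible = rev, lb = lb, ub = ub,
                      stringsAsFactors = FALSE),
    S = S, biomass_id = biomass, big_m = big_m)
}

.write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$species_id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="c" ',
             'boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>'),
      esc(model$mets$id[i]), esc(model$mets$name[i]),
      tolower(model$mets$external[i])))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (j in seq_len(nrow(model$rxns))) {
    lines <- c(lines,
      sprintf('      <parameter id="lb_%d" value="%.12g" constant="true"/>', j, model$rxns$lb[j]),
      sprintf('      <parameter id="ub_%d" value="%.12g" constant="true"/>', j, model$rxns$ub[j]))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_len(nrow(model$rxns))) {
    col <- model$S[, j]
    side <- function(idx, tag) {
      if (!length(idx)) return(character(0))
      c(sprintf('        <%s>', tag),
        vapply(idx, function(i) sprintf(
          '          <speciesReference species="%s" stoichiometry="%.12g" constant="true"/>',
          esc(rownames(model$S)[i]), abs(col[i])), ""),
        sprintf('        </%s>', tag))
    }
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">'),
      esc(model$rxns$id[j]), tolower(model$rxns$reversible[j]), j, j),
      side(which(col < 0), "listOfReactants"),
      side(which(col > 0), "listOfProducts"),
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(model$biomass_id)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  writeLines(lines, path)
}
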