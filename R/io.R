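#' Read a stoichiometric model from disk
#'
#' Two formats are supported: SBML Level 3 with the flux-bounds/objective
#' (fbc) package, and a plain tabular dialect designed to be human-diffable.
#'
#' The tabular dialect has one reaction per line,
#' ```
#' id : 2 A + B --> C ; lb, ub ; obj ; gpr
#' ```
#' with `<=>` marking reversible reactions, rational coefficients and bounds
#' written as `p/q` (or decimals, converted exactly), `inf`/`-inf` for
#' unbounded, and an optional directive line `boundary: X Y` naming the
#' boundary species. The `; obj` and `; gpr` fields are optional.
#'
#' @param path file path.
#' @param format `"sbml"` or `"tabular"` (default guessed from the
#'   extension: `.xml`/`.sbml` is SBML).
#' @return A `stoich_model`. A warning is raised when no objective
#'   coefficient is set anywhere (one must then be supplied at solve time).
#' @export
read_model <- function(path, format = c("auto", "sbml", "tabular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tabular"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  m <- switch(format, sbml = read_model_sbml(path), tabular = read_model_tab(path))
  if (all(vapply(m$reactions, function(r) r$obj$num == 0, logical(1)))) {
    warning("model has no objective coefficient; supply one at solve time")
  }
  m
}

#' Write a stoichiometric model to disk
#'
#' @param model a `stoich_model`.
#' @param path output file path.
#' @param format `"sbml"` or `"tabular"`; see [read_model()]. Bounds and
#'   coefficients round-trip exactly (rationals serialized as `p/q` in the
#'   tabular dialect).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  switch(format,
         tabular = write_model_tab(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# ---- tabular ---------------------------------------------------------------

fmt_bound <- function(b) {
  if (!bound_finite(b)) return(if (b > 0) "inf" else "-inf")
  format(b)
}

parse_bound <- function(s) {
  s <- trimws(s)
  if (s %in% c("inf", "+inf", "Inf")) return(Inf)
  if (s %in% c("-inf", "-Inf")) return(-Inf)
  rq_parse(s)
}

parse_side <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(list(sp = character(0), co = rq(numeric(0))))
  terms <- strsplit(s, "+", fixed = TRUE)[[1]]
  sp <- character(0); co <- list()
  for (t in terms) {
    t <- trimws(t)
    if (!nzchar(t)) stop("empty term in equation side: '", s, "'")
    parts <- strsplit(t, "[[:space:]]+")[[1]]
    if (length(parts) == 1) { sp <- c(sp, parts[1]); co <- c(co, list(rq(1))) }
    else if (length(parts) == 2) { sp <- c(sp, parts[2]); co <- c(co, list(rq_parse(parts[1]))) }
    else stop("cannot parse term: '", t, "'")
  }
  list(sp = sp, co = do.call(rq_c, co))
}

read_model_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  boundary <- character(0)
  rx <- list()
  order_sp <- character(0)
  for (ln in lines) {
    if (grepl("^boundary\\s*:", ln)) {
      boundary <- c(boundary, strsplit(trimws(sub("^boundary\\s*:", "", ln)),
                                       "[[:space:],]+")[[1]])
      next
    }
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) stop("cannot parse line (no 'id :'): ", ln)
    id <- trimws(substr(ln, 1, colon - 1))
    rest <- substr(ln, colon + 1, nchar(ln))
    fields <- strsplit(rest, ";", fixed = TRUE)[[1]]
    eqn <- trimws(fields[1])
    rev <- grepl("<=>", eqn, fixed = TRUE)
    arrow <- if (rev) "<=>" else "-->"
    if (!grepl(arrow, eqn, fixed = TRUE)) stop("reaction ", id, ": no arrow in '", eqn, "'")
    sides <- strsplit(eqn, arrow, fixed = TRUE)[[1]]
    if (length(sides) == 1) sides <- c(sides, "")
    lhs <- parse_side(sides[1]); rhs <- parse_side(sides[2])
    sp <- c(lhs$sp, rhs$sp)
    co <- rq_c(-lhs$co, rhs$co)
    # net coefficients for species on both sides
    usp <- unique(sp)
    net <- rq(numeric(length(usp)))
    for (i in seq_along(usp)) {
      ix <- which(sp == usp[i])
      acc <- rq(0); for (k in ix) acc <- acc + co[k]
      net[i] <- acc
    }
    attr(net, "species") <- usp
    lb <- NULL; ub <- NULL; obj <- rq(0); gpr <- NA_character_
    if (length(fields) >= 2 && nzchar(trimws(fields[2]))) {
      bs <- strsplit(fields[2], ",", fixed = TRUE)[[1]]
      if (length(bs) != 2) stop("reaction ", id, ": bounds must be 'lb, ub'")
      lb <- parse_bound(bs[1]); ub <- parse_bound(bs[2])
    }
    if (length(fields) >= 3 && nzchar(trimws(fields[3]))) obj <- rq_parse(fields[3])
    if (length(fields) >= 4 && nzchar(trimws(fields[4]))) gpr <- trimws(fields[4])
    if (is.null(lb)) lb <- if (rev) -Inf else 0
    if (is.null(ub)) ub <- Inf
    rx[[length(rx) + 1L]] <- fs_reaction(id, net, reversible = rev,
                                         lb = lb, ub = ub, obj = obj, gpr = gpr)
    order_sp <- union(order_sp, usp)
  }
  unknown <- setdiff(boundary, order_sp)
  if (length(unknown)) stop("boundary directive names unknown species: ",
                            paste(unknown, collapse = ", "))
  species <- data.frame(id = order_sp, boundary = order_sp %in% boundary)
  fs_model(species, rx)
}

fmt_side <- function(sp, co) {
  if (length(sp) == 0) return("")
  paste(mapply(function(s, i) {
    c1 <- co[i]
    if (isTRUE(c1 == rq(1))) s else paste(format(c1), s)
  }, sp, seq_along(sp)), collapse = " + ")
}

write_model_tab <- function(model, path) {
  out <- character(0)
  bnd <- model$species$id[model$species$boundary]
  if (length(bnd)) out <- c(out, paste("boundary:", paste(bnd, collapse = " ")))
  for (r in model$reactions) {
    sp <- attr(r$stoich, "species")
    neg <- which(r$stoich$num < 0); pos <- which(r$stoich$num > 0)
    lhs <- fmt_side(sp[neg], abs(r$stoich)[neg])
    rhs <- fmt_side(sp[pos], r$stoich[pos])
    arrow <- if (r$reversible) "<=>" else "-->"
    line <- sprintf("%s : %s %s %s ; %s, %s ; %s", r$id, lhs, arrow, rhs,
                    fmt_bound(r$lb), fmt_bound(r$ub), format(r$obj))
    if (!is.na(r$gpr)) line <- paste(line, ";", r$gpr)
    out <- c(out, line)
  }
  writeLines(out, path)
}

# ---- SBML L3 / fbc ---------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_num <- function(s) {
  if (s %in% c("INF", "inf")) return(Inf)
  if (s %in% c("-INF", "-inf")) return(-Inf)
  rq_from_decimal(as.numeric(s))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("SBML parse failure: no <model> element")

  params <- new.env(parent = emptyenv())
  for (p in xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)) {
    assign(xml2::xml_attr(p, "id"), sbml_num(xml2::xml_attr(p, "value")), envir = params)
  }
  gene_labels <- new.env(parent = emptyenv())
  for (g in xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)) {
    assign(xml2::xml_attr(g, "id"),
           xml2::xml_attr(g, "label") %||% xml2::xml_attr(g, "id"),
           envir = gene_labels)
  }

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    boundary = xml2::xml_attr(sp_nodes, "boundaryCondition") %in% c("true", "1"))

  obj_coeff <- list()
  active <- xml2::xml_attr(xml2::xml_find_first(mdl, ".//fbc:listOfObjectives", ns),
                           "activeObjective")
  for (o in xml2::xml_find_all(mdl, ".//fbc:listOfObjectives/fbc:objective", ns)) {
    oid <- xml2::xml_attr(o, "id")
    if (!is.na(active) && !is.na(oid) && oid != active) next
    for (fo in xml2::xml_find_all(o, ".//fbc:fluxObjective", ns)) {
      obj_coeff[[xml2::xml_attr(fo, "reaction")]] <-
        rq_from_decimal(as.numeric(xml2::xml_attr(fo, "coefficient")))
    }
  }

  gpr_tree_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- if (exists(ref, envir = gene_labels)) get(ref, envir = gene_labels) else ref
      return(lbl)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_tree_to_string, character(1))
    op <- if (nm == "and") " and " else if (nm == "or") " or " else
      stop("SBML parse failure: unsupported GPR node <", nm, ">")
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- list()
  for (rn in xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)) {
    id <- xml2::xml_attr(rn, "id")
    rev <- xml2::xml_attr(rn, "reversible") %in% c("true", "1")
    sp <- character(0); co <- list()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- c(sp, xml2::xml_attr(sr, "species"))
      co <- c(co, list(-rq_from_decimal(as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1"))))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- c(sp, xml2::xml_attr(sr, "species"))
      co <- c(co, list(rq_from_decimal(as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1"))))
    }
    if (length(sp) == 0) stop("SBML parse failure: reaction ", id, " has empty stoichiometry")
    st <- do.call(rq_c, co)
    attr(st, "species") <- sp
    lbp <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lbp) && exists(lbp, envir = params)) get(lbp, envir = params)
          else if (rev) -Inf else 0
    ub <- if (!is.na(ubp) && exists(ubp, envir = params)) get(ubp, envir = params) else Inf
    gpr_node <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpr_node, "xml_missing")) NA_character_ else gpr_tree_to_string(gpr_node)
    obj <- obj_coeff[[id]] %||% rq(0)
    rx[[length(rx) + 1L]] <- fs_reaction(id, st, reversible = rev,
                                         lb = lb, ub = ub, obj = obj, gpr = gpr)
  }
  fs_model(species, rx)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (is.atomic(a) && length(a) == 1 && is.na(a))) b else a
}

sbml_fmt <- function(b) {
  if (!bound_finite(b)) return(if (b > 0) "INF" else "-INF")
  # SBML carries doubles; emit enough digits to round-trip our rationals
  format(as.double(b), digits = 17)
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(los, "species",
      id = model$species$id[i],
      boundaryCondition = if (model$species$boundary[i]) "true" else "false",
      hasOnlySubstanceUnits = "false", constant = "false", compartment = "c")
  }

  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  bound_param <- function(j, which, b) {
    pid <- sprintf("%s_%s", which, fs_rxn_ids(model)[j])
    xml2::xml_add_child(lop, "parameter", id = pid, value = sbml_fmt(b),
                        constant = "true")
    pid
  }

  gpr_string_to_xml <- function(parent, tree) {
    if (is.character(tree)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef", "fbc:geneProduct" = gp_id(tree))
    } else {
      node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
      for (k in tree$args) gpr_string_to_xml(node, k)
    }
    invisible(NULL)
  }
  gp_id <- function(label) paste0("G_", gsub("[^A-Za-z0-9_]", "_", label))

  gprs <- lapply(model$reactions, `[[`, "gpr")
  all_proteins <- unique(unlist(lapply(gprs[!is.na(gprs)],
                                       function(g) gpr_proteins(parse_gpr(g)))))
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
      reversible = if (r$reversible) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bound_param(j, "lb", r$lb),
      "fbc:upperFluxBound" = bound_param(j, "ub", r$ub))
    sp <- attr(r$stoich, "species")
    neg <- which(r$stoich$num < 0); pos <- which(r$stoich$num > 0)
    if (length(neg)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in neg) xml2::xml_add_child(lre, "speciesReference", species = sp[k],
        stoichiometry = format(as.double(abs(r$stoich)[k]), digits = 17),
        constant = "true")
    }
    if (length(pos)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in pos) xml2::xml_add_child(lpr, "speciesReference", species = sp[k],
        stoichiometry = format(as.double(r$stoich[k]), digits = 17),
        constant = "true")
    }
    if (!is.na(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      gpr_string_to_xml(ga, parse_gpr(r$gpr))
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (r in model$reactions) {
    if (r$obj$num != 0) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = r$id,
                          "fbc:coefficient" = format(as.double(r$obj), digits = 17))
    }
  }
  if (length(all_proteins)) {
    lgp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (p in all_proteins) {
      xml2::xml_add_child(lgp, "fbc:geneProduct", "fbc:id" = gp_id(p), "fbc:label" = p)
    }
  }
  xml2::write_xml(doc, path)
}

#' Structural equality of two models
#'
#' Exact comparison of species (ids + boundary flags), reaction ids, order,
#' stoichiometry, reversibility, bounds, objective coefficients and GPRs.
#' Used to assert round-trips.
#'
#' @param a,b `stoich_model`s.
#' @return logical.
#' @export
fs_model_equal <- function(a, b) {
  if (!setequal(a$species$id, b$species$id)) return(FALSE)
  ord <- match(a$species$id, b$species$id)
  if (!identical(a$species$boundary, b$species$boundary[ord])) return(FALSE)
  if (!identical(fs_rxn_ids(a), fs_rxn_ids(b))) return(FALSE)
  for (id in fs_rxn_ids(a)) {
    ra <- a$reactions[[id]]; rb <- b$reactions[[id]]
    if (!identical(ra$reversible, rb$reversible)) return(FALSE)
    spa <- attr(ra$stoich, "species"); spb <- attr(rb$stoich, "species")
    if (!setequal(spa, spb)) return(FALSE)
    ord <- match(spa, spb)
    if (!all(ra$stoich == rb$stoich[ord])) return(FALSE)
    for (fld in c("lb", "ub")) {
      ba <- ra[[fld]]; bb <- rb[[fld]]
      if (bound_finite(ba) != bound_finite(bb)) return(FALSE)
      if (bound_finite(ba)) { if (!isTRUE(ba == bb)) return(FALSE) }
      else if (sign(ba) != sign(bb)) return(FALSE)
    }
    if (!isTRUE(ra$obj == rb$obj)) return(FALSE)
    if (!identical(is.na(ra$gpr), is.na(rb$gpr))) return(FALSE)
  }
  TRUE
}
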