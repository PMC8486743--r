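# Error conditions the CLI maps to distinct exit codes.
stop_parse <- function(...) {
  stop(structure(class = c("crnsim_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
stop_validation <- function(...) {
  stop(structure(class = c("crnsim_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Load a reaction network from a file
#'
#' Two formats are supported: SBML Level 2/3 (species, reactions,
#' stoichiometries, kinetic-law rate constants, boundary/constant flags)
#' and a plain tab-separated reaction-table dialect for small models (see
#' [read_reaction_table()]).  Reversible SBML reactions are split into two
#' irreversible reactions linked by `reverse_of`; boundary/constant SBML
#' species become constant generator pools.
#'
#' @param path model file.
#' @param format `"sbml"`, `"reaction-table"`, or `"auto"` (by extension:
#'   `.xml`/`.sbml` is SBML, anything else the reaction table).
#' @param pools_as_synthesis if TRUE, constant generator pools are replaced
#'   by equivalent pseudo synthesis reactions from the null complex (the
#'   pool's fixed concentration is folded into the rate constants of the
#'   reactions it feeds and the pool species is dropped).
#' @return a [crn].
#' @export
load_crn <- function(path, format = c("auto", "sbml", "reaction-table"),
                     pools_as_synthesis = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("model file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "reaction-table"
  net <- if (format == "sbml") read_sbml(path) else read_reaction_table(path)
  if (pools_as_synthesis) net <- pools_to_synthesis(net)
  net
}

#' Read a network from the reaction-table dialect
#'
#' A plain TSV with two blocks introduced by the header lines `# species`
#' and `# reactions` (any other `#` line is a comment):
#' \preformatted{
#' # species
#' A<TAB>1<TAB>0
#' B<TAB>1<TAB>0
#' C<TAB>0<TAB>0
#' # reactions
#' bind<TAB>A + B -> C<TAB>1<TAB>unbind
#' unbind<TAB>C -> A + B<TAB>1<TAB>bind
#' }
#' Species columns: id, initial concentration (nM), constant-pool flag
#' (0/1).  Reaction columns: id, equation (`"A + 2 B -> C"`, `0` denotes
#' the null complex), rate constant, and optionally the id of the reverse
#' direction (empty, `.` or `NA` for none).
#'
#' @param path file path.
#' @return a [crn].
#' @export
read_reaction_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  species <- list(); reactions <- list()
  for (ln in lines) {
    raw <- trimws(ln)
    if (raw == "") next
    if (grepl("^#", raw)) {
      low <- tolower(gsub("^#+\\s*", "", raw))
      if (startsWith(low, "species")) section <- "species"
      else if (startsWith(low, "reactions")) section <- "reactions"
      next
    }
    f <- trimws(strsplit(ln, "\t")[[1L]])
    if (section == "species") {
      if (length(f) < 2L)
        stop_parse("species line needs at least id and x0: ", ln)
      x0 <- suppressWarnings(as.numeric(f[2L]))
      if (is.na(x0)) stop_parse("bad initial concentration in: ", ln)
      species[[length(species) + 1L]] <-
        data.frame(id = f[1L], x0 = x0,
                   constant = length(f) >= 3L && f[3L] %in% c("1", "TRUE", "true"))
    } else if (section == "reactions") {
      if (length(f) < 3L)
        stop_parse("reaction line needs id, equation and k: ", ln)
      eq <- parse_equation(f[2L])
      k <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(k)) stop_parse("bad rate constant in: ", ln)
      rev <- if (length(f) >= 4L && !f[4L] %in% c("", ".", "NA"))
        f[4L] else NA_character_
      reactions[[length(reactions) + 1L]] <-
        list(id = f[1L], reactants = eq$reactants, products = eq$products,
             k = k, reverse_of = rev)
    } else {
      stop_parse("data line before any '# species' / '# reactions' header: ",
                 ln)
    }
  }
  if (length(species) == 0L) stop_parse("no species block in ", path)
  out <- tryCatch(crn(do.call(rbind, species), reactions),
                  error = function(e) stop_validation(conditionMessage(e)))
  out
}

# "A + 2 B -> C" -> list(reactants = c(A=1, B=2), products = c(C=1))
parse_equation <- function(eq) {
  halves <- strsplit(eq, "->", fixed = TRUE)[[1L]]
  if (length(halves) != 2L)
    stop_parse("equation must contain exactly one '->': ", eq)
  side <- function(s) {
    s <- trimws(s)
    if (s == "" || s == "0") return(integer(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
    st <- integer(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]+)\\s+(\\S.*)$", tm))[[1L]]
      if (length(m) == 3L) {
        cnt <- as.integer(m[2L]); sp <- m[3L]
      } else {
        cnt <- 1L; sp <- tm
      }
      if (sp == "") stop_parse("empty species name in term '", tm, "'")
      st[sp] <- (if (sp %in% names(st)) st[[sp]] else 0L) + cnt
    }
    st
  }
  list(reactants = side(halves[1L]), products = side(halves[2L]))
}

#' Write a network in the reaction-table dialect
#'
#' Rate constants and initial concentrations are printed with 17
#' significant digits so the written file round-trips bit-exactly through
#' [read_reaction_table()].
#'
#' @param x a [crn].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reaction_table <- function(x, path) {
  stopifnot(inherits(x, "crn"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# species\t(id\tx0\tconstant)", con)
  with(x$species, writeLines(sprintf("%s\t%.17g\t%d", id, x0,
                                     as.integer(constant)), con))
  writeLines("# reactions\t(id\tequation\tk\treverse_of)", con)
  for (rx in x$reactions)
    writeLines(sprintf("%s\t%s\t%.17g\t%s", rx$id, format_reaction(rx),
                       x$k[[rx$id]],
                       if (is.na(rx$reverse_of)) "." else rx$reverse_of),
               con)
  invisible(path)
}

#' Read a network from SBML
#'
#' Supports the SBML Level 2/3 subset used by mass-action signalling
#' models: `listOfSpecies` (id, `initialConcentration`/`initialAmount`,
#' `boundaryCondition`/`constant` flags), `listOfReactions` with reactant
#' and product `speciesReference` stoichiometries, and per-reaction
#' kinetic-law parameters holding the mass-action rate constants.
#' Reversible reactions must carry two kinetic parameters (forward then
#' reverse; names containing `f`/`r` such as `kf`/`kr` disambiguate) and
#' are split into two irreversible reactions `<id>` and `<id>_rev` linked
#' by `reverse_of`.  Other kinetic laws, compartment volumes, events and
#' assignment rules are out of scope.
#'
#' @param path SBML file.
#' @return a [crn].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_parse("failed to parse SBML: ",
                                                 conditionMessage(e)))
  sp_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop_parse("no species found in ", path)
  attr_or <- function(node, name, default) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  species <- do.call(rbind, lapply(sp_nodes, function(nd) {
    x0 <- as.numeric(attr_or(nd, "initialConcentration",
                             attr_or(nd, "initialAmount", "0")))
    data.frame(
      id = xml2::xml_attr(nd, "id"),
      x0 = x0,
      constant = attr_or(nd, "boundaryCondition", "false") == "true" |
        attr_or(nd, "constant", "false") == "true")
  }))
  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  reactions <- list()
  for (nd in rx_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    reversible <- attr_or(nd, "reversible", "true") == "true"
    refs <- function(which) {
      rr <- xml2::xml_find_all(nd, paste0(
        "./*[local-name()='", which, "']/*[local-name()='speciesReference']"))
      if (length(rr) == 0L) return(integer(0))
      st <- as.integer(vapply(rr, function(r)
        as.numeric(attr_or(r, "stoichiometry", "1")), numeric(1)))
      stats::setNames(st, vapply(rr, xml2::xml_attr, "", "species"))
    }
    reac <- refs("listOfReactants")
    prod <- refs("listOfProducts")
    pars <- xml2::xml_find_all(nd, paste0(
      ".//*[local-name()='kineticLaw']//*[",
      "local-name()='parameter' or local-name()='localParameter']"))
    if (length(pars) == 0L)
      stop_validation("reaction '", rid, "': no kinetic-law rate constant")
    pnames <- vapply(pars, function(p)
      attr_or(p, "id", attr_or(p, "name", "")), "")
    pvals <- vapply(pars, function(p) as.numeric(xml2::xml_attr(p, "value")),
                    numeric(1))
    if (anyNA(pvals))
      stop_validation("reaction '", rid, "': missing rate-constant value")
    if (reversible) {
      if (length(pars) < 2L)
        stop_validation("reversible reaction '", rid,
                        "': needs forward and reverse rate constants")
      fw <- grep("f", pnames, ignore.case = TRUE)
      bw <- grep("r$|rev|_r|kr", pnames, ignore.case = TRUE)
      i_f <- if (length(fw)) fw[1L] else 1L
      i_r <- if (length(setdiff(bw, i_f))) setdiff(bw, i_f)[1L] else
        setdiff(seq_along(pvals), i_f)[1L]
      reactions <- c(reactions, list(
        list(id = rid, reactants = reac, products = prod,
             k = pvals[i_f], reverse_of = paste0(rid, "_rev")),
        list(id = paste0(rid, "_rev"), reactants = prod, products = reac,
             k = pvals[i_r], reverse_of = rid)))
    } else {
      reactions <- c(reactions, list(
        list(id = rid, reactants = reac, products = prod,
             k = pvals[1L], reverse_of = NA_character_)))
    }
  }
  tryCatch(crn(species, reactions),
           error = function(e) stop_validation(conditionMessage(e)))
}

#' Replace constant generator pools by pseudo synthesis reactions
#'
#' A constant pool species G feeding a reaction `G -> P` at fixed
#' concentration g produces P at the constant rate `k * g`; the same
#' dynamics are obtained with the pseudo reaction `0 -> P` with rate
#' constant `k * g` and no G.  This folds every constant pool into the
#' rate constants of the reactions it touches and drops the pool species.
#'
#' @param x a [crn].
#' @return an equivalent [crn] without constant-pool species.
#' @export
pools_to_synthesis <- function(x) {
  stopifnot(inherits(x, "crn"))
  pools <- x$species$id[x$species$constant]
  if (length(pools) == 0L) return(x)
  conc <- stats::setNames(x$species$x0, x$species$id)
  reactions <- lapply(x$reactions, function(rx) {
    rx$k <- x$k[[rx$id]]
    for (g in intersect(names(rx$reactants), pools)) {
      rx$k <- rx$k * conc[[g]] ^ rx$reactants[[g]]
      rx$reactants <- rx$reactants[names(rx$reactants) != g]
    }
    rx$products <- rx$products[!names(rx$products) %in% pools]
    rx
  })
  species <- x$species[!x$species$constant, , drop = FALSE]
  crn(species, reactions)
}
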