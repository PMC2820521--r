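#' Export a network as SBML Level 3
#'
#' Writes species, a single spine compartment and every elementary
#' reaction (binding reactions as one reversible reaction; enzymatic
#' reactions as their two elementary steps) with mass-action kinetic laws,
#' for cross-validation of the model in independent simulators. Export
#' only; SBML import is out of scope.
#'
#' @param net A [reaction_network()].
#' @param path Output file path (`.xml`).
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(net, path, model_id = "spine_model") {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = model_id)

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "spine", spatialDimensions = "3",
                      size = format(net$volume), constant = "true")

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    xml2::xml_add_child(
      ls, "species",
      id = net$species$name[i], compartment = "spine",
      initialConcentration = sprintf("%.17g", net$species$conc[i]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = tolower(as.character(net$species$clamped[i])),
      constant = "false")
  }

  lp <- xml2::xml_add_child(model, "listOfParameters")
  lr <- xml2::xml_add_child(model, "listOfReactions")
  kid <- 0
  add_param <- function(value) {
    kid <<- kid + 1
    id <- paste0("k", kid)
    xml2::xml_add_child(lp, "parameter", id = id,
                        value = sprintf("%.17g", value), constant = "true")
    id
  }
  add_reaction <- function(id, reactants, products, rate_expr) {
    rn <- xml2::xml_add_child(lr, "reaction", id = id, reversible = "false")
    lrx <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in reactants)
      xml2::xml_add_child(lrx, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    lpx <- xml2::xml_add_child(rn, "listOfProducts")
    for (s in products)
      xml2::xml_add_child(lpx, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    for (ci in rate_expr) xml2::xml_add_child(ap, "ci", ci)
  }

  rid <- 0
  for (r in net$reactions) {
    rid <- rid + 1
    if (inherits(r, "binding_reaction")) {
      add_reaction(sprintf("r%d_f", rid), c(r$a, r$b), r$ab,
                   c(add_param(r$kf), "spine", r$a, r$b))
      add_reaction(sprintf("r%d_b", rid), r$ab, c(r$a, r$b),
                   c(add_param(r$kb), "spine", r$ab))
    } else {
      add_reaction(sprintf("r%d_on", rid), c(r$enzyme, r$substrate),
                   r$complex, c(add_param(r$kf), "spine", r$enzyme,
                                r$substrate))
      add_reaction(sprintf("r%d_off", rid), r$complex,
                   c(r$enzyme, r$substrate),
                   c(add_param(r$kb), "spine", r$complex))
      add_reaction(sprintf("r%d_cat", rid), r$complex,
                   c(r$enzyme, r$product),
                   c(add_param(r$kcat), "spine", r$complex))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
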