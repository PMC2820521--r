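#' Load the model parameter tables
#'
#' Reads and validates the three delimited-text tables defining the spine
#' model: initial concentrations (columns `species, conc, clamped, note`),
#' enzymatic reactions (`enzyme, substrate, product, km, kcat, kf, kb,
#' group, provenance, note`) and binding reactions (`a, b, ab, kd, tau, kf,
#' kb, group, provenance, note`). When `kf`/`kb` are given they take
#' precedence over the thermodynamic (`km`/`kcat`, `kd`/`tau`)
#' parameterization. The `group` column marks reactions sharing one rate
#' parameter set; the `provenance` column records whether constants came
#' from literature or were hand-tuned (bookkeeping only).
#'
#' @param concentrations,enzymatic,binding Paths to the three tables;
#'   defaults are the tables shipped with the package.
#' @return A validated object of class `"model_tables"`.
#' @export
load_tables <- function(
    concentrations = spinesim_table("initial_concentrations.csv"),
    enzymatic = spinesim_table("enzymatic_reactions.csv"),
    binding = spinesim_table("binding_reactions.csv")) {
  rd <- function(path, cols) {
    if (!file.exists(path)) stop("no such table: ", path)
    x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
    if (nrow(x) == 0) stop("empty table: ", path)
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("table ", path, " lacks columns: ", paste(miss, collapse = ", "))
    x
  }
  s1 <- rd(concentrations, c("species", "conc"))
  if (is.null(s1$clamped)) s1$clamped <- FALSE
  s2 <- rd(enzymatic, c("enzyme", "substrate", "product", "km", "kcat"))
  s3 <- rd(binding, c("a", "b", "ab", "kd", "tau"))
  for (tb in list(s2, s3)) {
    bad <- which(!stats::complete.cases(tb[, c(1, 2, 3)]))
    if (length(bad)) stop("malformed reaction row(s): ",
                          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(s1$species))
    stop("duplicate species in concentration table: ",
         paste(unique(s1$species[duplicated(s1$species)]), collapse = ", "))

  declared <- s1$species
  created <- c(s3$ab, paste0(s2$enzyme, ".", s2$substrate))
  referenced <- unique(c(s2$enzyme, s2$substrate, s2$product,
                         s3$a, s3$b, s3$ab))
  unknown <- setdiff(referenced, c(declared, created))
  if (length(unknown))
    stop("species referenced but never initialized: ",
         paste(unknown, collapse = ", "))

  structure(list(concentrations = s1, enzymatic = s2, binding = s3),
            class = "model_tables")
}

#' Path to a packaged model table
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
spinesim_table <- function(file) {
  p <- system.file("extdata", file, package = "spinesim")
  if (p == "") stop("packaged table not found: ", file)
  p
}

#' @export
print.model_tables <- function(x, ...) {
  cat("model_tables: ", nrow(x$concentrations), " species, ",
      nrow(x$enzymatic), " enzymatic + ", nrow(x$binding),
      " binding reactions\n", sep = "")
  invisible(x)
}

#' Build the striatal-spine reaction network from parameter tables
#'
#' Realizes the full D1R-spine cascade: dopamine-D1R-Golf-AC5-cAMP-PKA with
#' the PKA-PDE-cAMP negative feedback; calcium inhibition of AC5 and
#' calmodulin-enhanced PDE; Ca/CaM activation of CaMKII (with Thr286
#' autophosphorylation and PP1 dephosphorylation), PP2B and PP2A (calcium-
#' and PKA-activated B-subunit routes); the PP2B-CK1-Cdk5 pathway (CK1
#' self-inhibits by autophosphorylation, PP2B reactivates it, CK1 activates
#' Cdk5 in one collapsed enzymatic step); the 8-state DARPP-32
#' phospho-model over Thr34/Thr75/Ser137 with phospho-Thr34 inhibiting PP1
#' and phospho-Thr75 sequestering the PKA catalytic subunit; inhibitor-1;
#' and the AMPA-receptor trafficking scheme (serial Ser845/Ser831
#' phosphorylation, anchor binding, membrane insertion of phosphorylated
#' receptors, removal of dephosphorylated ones, bulk-pool exchange).
#'
#' @param tables A [load_tables()] object (defaults to the packaged model).
#' @return A [reaction_network()] carrying additional attributes:
#'   `proteins` (named list mapping proteins to their free states) and
#'   `pathways` (named list of reaction labels removable with
#'   [ablate_pathway()]).
#' @export
build_network <- function(tables = load_tables()) {
  stopifnot(inherits(tables, "model_tables"))
  s1 <- tables$concentrations
  sp <- lapply(seq_len(nrow(s1)), function(i)
    species(s1$species[i], s1$conc[i], clamped = isTRUE(s1$clamped[i])))

  rx <- list()
  for (i in seq_len(nrow(tables$binding))) {
    r <- tables$binding[i, ]
    rx[[length(rx) + 1L]] <- binding_reaction(
      r$a, r$b, r$ab,
      kf = if (is.finite(r$kf)) r$kf else NULL,
      kb = if (is.finite(r$kb)) r$kb else NULL,
      kd = if (is.finite(r$kd)) r$kd else NULL,
      tau = if (is.finite(r$tau)) r$tau else NULL,
      group = r$group)
  }
  for (i in seq_len(nrow(tables$enzymatic))) {
    r <- tables$enzymatic[i, ]
    rx[[length(rx) + 1L]] <- enzymatic_reaction(
      r$enzyme, r$substrate, r$product,
      kf = if (is.finite(r$kf)) r$kf else NULL,
      kb = if (is.finite(r$kb)) r$kb else NULL,
      kcat = r$kcat,
      km = if (is.finite(r$km)) r$km else NULL,
      group = r$group)
  }

  net <- reaction_network(sp, rx)
  net$inputs <- c(calcium = "Ca", dopamine = "DA")
  net$proteins <- list(
    DARPP32 = c("D000", "D34", "D75", "D137", "D34_75", "D34_137",
                "D75_137", "D34_75_137"),
    CaM = "CaM", CaMKII = "CaMKII", PP1 = "PP1", PP2A = "PP2A",
    PP2B = "PP2B", CK1 = "CK1", Cdk5 = "Cdk5", I1 = "I1",
    AMPAR = c("AMPAR", "AMPARp845", "AMPARpp", "AMPARbulk"),
    D1R = "D1R", AC5 = "AC5", PDE = "PDE")
  net$pathways <- list(
    ck1_cdk5 = "CK1: Cdk5->Cdk5act",
    camkii_s831 = "CaMKIIpCaM: AMPARp845->AMPARpp",
    pka_pp2a = "PKAc: PP2A->PP2Ap")
  net$membrane_pool <- c("AMPARm", "AMPARp845m", "AMPARppm")
  net
}

#' Knock out a protein
#'
#' Emulates a genetic knockout by zeroing and clamping every species that
#' carries the protein (its conservation-law support: free states plus all
#' complexes). Reactions are retained; fluxes through them vanish.
#'
#' @param net A network from [build_network()].
#' @param protein Protein name from `net$proteins` (e.g. `"DARPP32"`).
#' @return The modified network.
#' @export
knockout <- function(net, protein) {
  states <- net$proteins[[protein]]
  if (is.null(states)) stop("unknown protein: ", protein)
  law <- protein_moiety(net, states)
  set_clamp(net, names(law), value = 0)
}

#' Remove a documented pathway from the network
#'
#' @param net A network from [build_network()].
#' @param pathway_id Name from `net$pathways`, or a character vector of
#'   reaction labels; an empty vector is a no-op.
#' @return The revalidated network without the listed reactions.
#' @export
ablate_pathway <- function(net, pathway_id) {
  labels <- if (length(pathway_id) == 1L && pathway_id %in% names(net$pathways))
    net$pathways[[pathway_id]]
  else if (length(pathway_id) == 0L) character(0)
  else if (all(pathway_id %in% vapply(net$reactions, `[[`, "", "name")))
    pathway_id
  else stop("unknown pathway: ", paste(pathway_id, collapse = ", "))
  if (length(labels) == 0L) return(net)
  keep <- !vapply(net$reactions, function(r) r$name %in% labels, TRUE)
  net$reactions <- net$reactions[keep]
  # drop orphaned ES complexes, keep everything else
  rebuilt <- .index_network(net)
  rebuilt
}
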