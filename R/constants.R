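# Packaged gene lists and analysis constants. These are the defaults used by
# the clustering and engram modules; all of them can be overridden through the
# configuration block (see `default_config()`), so the numbers live here and
# nowhere else in the code.

#' Immediate-early genes excluded from feature selection
#'
#' The 53 activity-regulated genes removed before feature selection, so that
#' clusters reflect cell identity and not the activation state of individual
#' cells.
#'
#' @return Character vector of 53 gene symbols.
#' @export
ieg_exclusion_genes <- function() {
  c("Btg2", "Jun", "Egr4", "Fosb", "Junb", "Gadd45g", "Fos", "Arc",
    "Nr4a1", "Npas4", "Coq10b", "Tns1", "Per2", "Ptgs2", "Rnd3",
    "Tnfaip6", "Srxn1", "Tiparp", "Ccnl1", "Mcl1", "Dnajb5", "Nr4a3",
    "Fosl2", "Nptx2", "Rasl11a", "Mest", "Sertad1", "Egr2", "Midn",
    "Gadd45b", "Dusp6", "Irs2", "Plat", "Ier2", "Rrad", "Tpbg",
    "Csrnp1", "Peli1", "Per1", "Kdm6b", "Inhba", "Plk2", "Ifrd1",
    "Baz1a", "Trib1", "Pim3", "Lrrk2", "Dusp1", "Cdkn1a", "Pim1",
    "Sik1", "Frat2", "Dusp5")
}

#' Sex-linked genes excluded from feature selection
#' @return Character vector of 6 gene symbols.
#' @export
sex_genes <- function() {
  c("Xist", "Tsix", "Eif2s3y", "Ddx3y", "Uty", "Kdm5d")
}

#' Non-neuronal marker genes
#'
#' The 25-gene list used to recognise (and, in the neuronal stream, exclude)
#' non-neuronal cells: microglia/immune, astrocyte, vascular, oligodendrocyte
#' and blood markers.
#'
#' @return Character vector of 25 gene symbols.
#' @export
nonneuronal_markers <- function() {
  c("C1qc", "C1qa", "C1qb", "Gja1", "Cx3cr1", "Acta2", "Ly6c1", "Mfge8",
    "Plxnb3", "Cldn11", "Aqp4", "Vtn", "Cldn5", "Pdgfrb", "Flt1",
    "Slc25a18", "Pdgfra", "Foxj1", "Olig1", "Olig2", "Sox10",
    "Hbb-bs", "Hbb-bt", "Hba-a2", "Ttr")
}

#' Immediate-early-gene activity panel
#'
#' The eight IEGs used for percentile-based activation calling and the
#' cluster IEG score.
#'
#' @return Character vector of 8 gene symbols.
#' @export
ieg_panel <- function() {
  c("Arc", "Bdnf", "Btg2", "Fos", "Fosl2", "Homer1", "Npas4", "Nr4a1")
}

#' Construct a marker set
#'
#' @param class Class name the markers vote for.
#' @param genes Nonempty character vector of gene symbols.
#' @param role One of `"neuron-class"`, `"non-neuronal-category"`,
#'   `"exclusion"`.
#' @return A `marker_set` list.
#' @export
marker_set <- function(class, genes,
                       role = c("neuron-class", "non-neuronal-category",
                                "exclusion")) {
  role <- match.arg(role)
  if (length(genes) == 0L) stopf("marker set '%s' has an empty gene list", class)
  structure(list(class = class, genes = as.character(genes), role = role),
            class = "marker_set")
}

#' Default neuron-class marker sets
#'
#' Gad2 votes GABA, Slc17a7 votes VGLUT1, Slc17a6 votes VGLUT2, and the
#' pooled non-neuronal marker list votes NonNeuronal.
#'
#' @return List of [marker_set()] objects.
#' @export
neuron_class_markers <- function() {
  list(
    marker_set("GABA",   "Gad2",    "neuron-class"),
    marker_set("VGLUT1", "Slc17a7", "neuron-class"),
    marker_set("VGLUT2", "Slc17a6", "neuron-class"),
    marker_set("NonNeuronal", nonneuronal_markers(), "non-neuronal-category")
  )
}

#' Default non-neuronal category marker sets
#' @return List of [marker_set()] objects (immune, astrocyte, vascular,
#'   oligodendrocyte, blood).
#' @export
nonneuronal_class_markers <- function() {
  list(
    marker_set("immune", c("C1qc", "C1qa", "C1qb", "Mrc1", "Pf4", "Cx3cr1"),
               "non-neuronal-category"),
    marker_set("astrocyte", c("Gja1", "Aqp4", "Foxj1", "Aldoc", "Mfge8",
                              "Slc25a18"), "non-neuronal-category"),
    marker_set("vascular", c("Vtn", "Cldn5", "Pdgfrb", "Flt1", "Acta2",
                             "Ly6c1"), "non-neuronal-category"),
    marker_set("oligodendrocyte", c("Plxnb3", "Cldn11", "Olig1", "Olig2",
                                    "Sox10", "Pdgfra"),
               "non-neuronal-category"),
    marker_set("blood", c("Hbb-bs", "Hbb-bt", "Hba-a2", "Ttr"), "exclusion")
  )
}

#' Default learning-related gene modules
#'
#' Seven functional groups of genes associated with activity-dependent
#' transcription (plus their union, `all_combined`), used by the module
#' correlation score. The lists are representative, editable defaults; any
#' named list of gene vectors can be supplied in their place.
#'
#' @return Named list of character vectors.
#' @export
learning_module_sets <- function() {
  mods <- list(
    IEG = c(ieg_panel(), "Junb", "Egr1", "Egr2", "Jun", "Fosb",
            "Nr4a3", "Nptx2", "Per1", "Dusp1", "Gadd45b"),
    learning_memory = c("Bdnf", "Creb1", "Camk2a", "Grin1", "Grin2a",
                        "Grin2b", "Ntrk2", "Ppp3ca", "Syn1", "Nlgn1",
                        "Nrxn1", "Shank3", "Dlg4", "Snap25", "Syt1"),
    glutamate_receptors = c("Gria1", "Gria2", "Gria3", "Gria4", "Grin1",
                            "Grin2a", "Grin2b", "Grm1", "Grm5", "Grik2"),
    gaba_receptors = c("Gabra1", "Gabra2", "Gabrb1", "Gabrb2", "Gabrb3",
                       "Gabrg2", "Gabbr1", "Gabbr2"),
    k_channels = c("Kcna1", "Kcna2", "Kcnb1", "Kcnc1", "Kcnd2", "Kcnj3",
                   "Kcnma1", "Kcnq2"),
    ca_channels = c("Cacna1a", "Cacna1b", "Cacna1c", "Cacna1e",
                    "Cacna2d1", "Cacnb2", "Cacng2"),
    semaphorins = c("Sema3a", "Sema3e", "Sema4d", "Sema5a", "Sema6a",
                    "Sema7a", "Plxna1", "Nrp1")
  )
  mods$all_combined <- sort(unique(unlist(mods)))
  mods
}

# Normalization scale: every cell vector is normalized to length 1 and then
# multiplied by this constant.
NORMALIZATION_SCALE <- 20000
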