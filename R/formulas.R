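# Built-in list of real small-molecule formulas used by the synthetic
# association-table generator. Names are common compound names; values are
# neutral molecular formulas. Covers amino acids, sugars, organic and bile
# acids, SCFAs, nucleosides, vitamins and common microbial co-metabolites.

#' Built-in small-molecule formulas
#'
#' A named character vector of neutral molecular formulas for common plasma
#' and gut-microbial metabolites. Used as the compound pool by
#' [generate_association_table()]; also convenient as test input for
#' [formula_mass()].
#'
#' @return Named character vector (compound name -> formula).
#' @export
#' @examples
#' head(builtin_formulas())
builtin_formulas <- function() {
  c(
    glycine = "C2H5NO2", alanine = "C3H7NO2", serine = "C3H7NO3",
    proline = "C5H9NO2", valine = "C5H11NO2", threonine = "C4H9NO3",
    cysteine = "C3H7NO2S", leucine = "C6H13NO2", isoleucine = "C6H13NO2",
    asparagine = "C4H8N2O3", aspartate = "C4H7NO4", glutamine = "C5H10N2O3",
    glutamate = "C5H9NO4", lysine = "C6H14N2O2", methionine = "C5H11NO2S",
    histidine = "C6H9N3O2", phenylalanine = "C9H11NO2",
    arginine = "C6H14N4O2", tyrosine = "C9H11NO3", tryptophan = "C11H12N2O2",
    ornithine = "C5H12N2O2", citrulline = "C6H13N3O3",
    taurine = "C2H7NO3S", creatinine = "C4H7N3O", creatine = "C4H9N3O2",
    carnitine = "C7H15NO3", acetylcarnitine = "C9H17NO4",
    choline = "C5H13NO", betaine = "C5H11NO2", sarcosine = "C3H7NO2",
    glucose = "C6H12O6", fructose = "C6H12O6", galactose = "C6H12O6",
    ribose = "C5H10O5", sucrose = "C12H22O11", lactose = "C12H22O11",
    inositol = "C6H12O6", glycerol = "C3H8O3", sorbitol = "C6H14O6",
    lactate = "C3H6O3", pyruvate = "C3H4O3", citrate = "C6H8O7",
    succinate = "C4H6O4", fumarate = "C4H4O4", malate = "C4H6O5",
    oxaloacetate = "C4H4O5", alphaketoglutarate = "C5H6O5",
    glyoxylate = "C2H2O3", oxalate = "C2H2O4",
    acetate = "C2H4O2", propionate = "C3H6O2", butyrate = "C4H8O2",
    valerate = "C5H10O2", hexanoate = "C6H12O2", formate = "CH2O2",
    cholate = "C24H40O5", chenodeoxycholate = "C24H40O4",
    deoxycholate = "C24H40O4", lithocholate = "C24H40O3",
    ursodeoxycholate = "C24H40O4", glycocholate = "C26H43NO6",
    taurocholate = "C26H45NO7S",
    palmitate = "C16H32O2", stearate = "C18H36O2", oleate = "C18H34O2",
    linoleate = "C18H32O2", arachidonate = "C20H32O2",
    myristate = "C14H28O2", laurate = "C12H24O2",
    adenine = "C5H5N5", guanine = "C5H5N5O", hypoxanthine = "C5H4N4O",
    xanthine = "C5H4N4O2", uracil = "C4H4N2O2", thymine = "C5H6N2O2",
    cytosine = "C4H5N3O", adenosine = "C10H13N5O4", inosine = "C10H12N4O5",
    uridine = "C9H12N2O6", urate = "C5H4N4O3", allantoin = "C4H6N4O3",
    nicotinamide = "C6H6N2O", nicotinate = "C6H5NO2",
    pantothenate = "C9H17NO5", riboflavin = "C17H20N4O6",
    thiamine = "C12H16N4OS", pyridoxine = "C8H11NO3", biotin = "C10H16N2O3S",
    ascorbate = "C6H8O6", folate = "C19H19N7O6",
    indole = "C8H7N", indoxylsulfate = "C8H7NO4S",
    indolepropionate = "C11H11NO2", indoleacetate = "C10H9NO2",
    hippurate = "C9H9NO3", phenylacetate = "C8H8O2",
    pcresolsulfate = "C7H8O4S", benzoate = "C7H6O2",
    trimethylamine = "C3H9N", tmao = "C3H9NO",
    putrescine = "C4H12N2", cadaverine = "C5H14N2", spermidine = "C7H19N3",
    histamine = "C5H9N3", serotonin = "C10H12N2O", kynurenine = "C10H12N2O3",
    urea = "CH4N2O", uridinemonophosphate = "C9H13N2O9P",
    glycerophosphocholine = "C8H20NO6P", phosphocholine = "C5H14NO4P",
    cholesterol = "C27H46O", bilirubin = "C33H36N4O6"
  )
}
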