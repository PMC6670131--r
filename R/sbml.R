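# SBML Level 3 Version 2 (core) export. Only writing is supported; the
# serializer covers exactly the constructs this network needs (constant
# parameters, unit concentrations in one compartment, mass-action /
# Michaelis / Hill kinetic laws with modifier species).

.mmlCi <- function(x) paste0("<ci> ", x, " </ci>")
.mmlApply <- function(op, ...) paste0("<apply><", op, "/>",
                                      paste0(..., collapse = ""),
                                      "</apply>")
.mmlTimes <- function(...) .mmlApply("times", c(...))
.mmlPlus <- function(...) .mmlApply("plus", c(...))
.mmlDivide <- function(a, b) .mmlApply("divide", c(a, b))
.mmlPower <- function(a, b) .mmlApply("power", c(a, b))

# MathML kinetic law for one reaction id
.sbmlKineticLaw <- function(id, mmp13Hill) {
  r <- Filter(function(z) z$id == id, .REACTIONS)[[1]]
  p <- .mmlCi(r$param)
  law <- switch(r$kind,
    "zeroth-order" = if (id == "r24")
      .mmlTimes(p, .mmlPlus(.mmlCi("Bcat_TCF"), .mmlCi("Bcat")))
    else p,
    "first-order" = if (id == "r24")
      .mmlTimes(p, .mmlPlus(.mmlCi("Bcat_TCF"), .mmlCi("Bcat")))
    else .mmlTimes(p, .mmlCi(r$reactants[1])),
    "second-order" = if (id == "r10")
      .mmlTimes(p, .mmlCi("APC_Axin_GSK3"), .mmlCi("Dsh_a"))
    else .mmlTimes(p, .mmlCi(r$reactants[1]), .mmlCi(r$reactants[2])),
    "Michaelis-type" = .mmlDivide(
      .mmlTimes(p, .mmlCi("Wnt_Fzl_LRP56"), .mmlCi("Dsh_i")),
      .mmlPlus(.mmlCi("K8"), .mmlCi("Dsh_i"))),
    "Hill-repression" = .mmlDivide(
      .mmlTimes(p, .mmlPower(.mmlCi("K3"), .mmlCi("m3"))),
      .mmlPlus(.mmlPower(.mmlCi("K3"), .mmlCi("m3")),
               .mmlPower(.mmlCi("Hotair"), .mmlCi("m3")))),
    "Hill-activation" = if (mmp13Hill == "activating")
      .mmlDivide(
        .mmlTimes(p, .mmlPower(.mmlCi("Bcat_TCF"), .mmlCi("m27"))),
        .mmlPlus(.mmlPower(.mmlCi("K27"), .mmlCi("m27")),
                 .mmlPower(.mmlCi("Bcat_TCF"), .mmlCi("m27"))))
    else
      .mmlDivide(
        .mmlTimes(p, .mmlPower(.mmlCi("K27"), .mmlCi("m27"))),
        .mmlPlus(.mmlPower(.mmlCi("K27"), .mmlCi("m27")),
                 .mmlPower(.mmlCi("Bcat_TCF"), .mmlCi("m27")))))
  law
}

# modifier species: enter the rate law without being converted
.SBML_MODIFIERS <- list(
  r3 = "Hotair", r8 = "Wnt_Fzl_LRP56", r10 = "Dsh_a",
  r24 = c("Bcat_TCF", "Bcat"), r27 = "Bcat_TCF")

#' Export the network as SBML Level 3
#'
#' Writes species (with initial concentrations), the 42 constant
#' parameters, and the 37 reactions with stoichiometry, modifiers and
#' MathML kinetic laws. The document is parsed back before writing to
#' guarantee well-formed XML. Import is not supported.
#'
#' @param path output file path (.xml).
#' @param params a [WntParameterSet-class].
#' @param init named initial-state vector.
#' @param mmp13Hill regulatory form of the MMP-13 synthesis step.
#' @return the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' exportSBML(f)
#' @export
exportSBML <- function(path, params = defaultParameters(),
                       init = initialState(),
                       mmp13Hill = c("activating", "printed")) {
  mmp13Hill <- match.arg(mmp13Hill)
  init <- .checkState(init)[1, ]
  pv <- paramValues(params)
  sp <- paste0(sprintf(
    '      <species id="%s" compartment="cell" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    speciesNames(), init[speciesNames()]), collapse = "\n")
  pars <- paste0(sprintf(
    '      <parameter id="%s" value="%.17g" constant="true"/>',
    names(pv), pv), collapse = "\n")
  rxn <- vapply(.REACTIONS, function(r) {
    refs <- function(species, tag) {
      if (!length(species)) return("")
      inner <- paste0(sprintf(
        '          <speciesReference species="%s" stoichiometry="1" constant="true"/>',
        species), collapse = "\n")
      sprintf("        <listOf%s>\n%s\n        </listOf%s>",
              tag, inner, tag)
    }
    mods <- .SBML_MODIFIERS[[r$id]]
    modXml <- if (is.null(mods)) "" else sprintf(
      "        <listOfModifiers>\n%s\n        </listOfModifiers>",
      paste0(sprintf(
        '          <modifierSpeciesReference species="%s"/>', mods),
        collapse = "\n"))
    parts <- c(refs(r$reactants, "Reactants"), refs(r$products, "Products"),
               modXml)
    parts <- parts[nzchar(parts)]
    sprintf(paste0(
      '      <reaction id="%s" reversible="false">\n%s\n',
      '        <kineticLaw>\n',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
      '            %s\n          </math>\n        </kineticLaw>\n',
      '      </reaction>'),
      r$id, paste0(parts, collapse = "\n"),
      .sbmlKineticLaw(r$id, mmp13Hill))
  }, character(1))
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="hotair_wnt_bcatenin_mmp13" name="HOTAIR-mediated Wnt/beta-catenin pathway" timeUnits="time" substanceUnits="substance" extentUnits="substance">
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
%s
    </listOfSpecies>
    <listOfParameters>
%s
    </listOfParameters>
    <listOfReactions>
%s
    </listOfReactions>
  </model>
</sbml>', sp, pars, paste0(rxn, collapse = "\n"))
  parsed <- xml2::read_xml(doc)  # fails on malformed output
  xml2::write_xml(parsed, path)
  invisible(path)
}
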