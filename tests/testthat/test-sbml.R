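test_that("SBML export carries the complete network", {
  f <- tempfile(fileext = ".xml")
  on.exit(unlink(f))
  exportSBML(f)
  doc <- xml2::read_xml(f)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  expect_length(xml2::xml_find_all(doc, ".//s:species", ns), 25)
  expect_length(xml2::xml_find_all(doc, ".//s:reaction", ns), 37)
  expect_length(xml2::xml_find_all(doc, ".//s:parameter", ns), 42)
  expect_length(xml2::xml_find_all(doc, ".//s:kineticLaw", ns), 37)
  # initial concentrations survive
  gsk <- xml2::xml_find_first(doc, ".//s:species[@id='GSK3']", ns)
  expect_equal(as.numeric(xml2::xml_attr(gsk, "initialConcentration")), 50)
  # the induced Axin synthesis step lists its transcriptional effectors
  r24 <- xml2::xml_find_first(doc, ".//s:reaction[@id='r24']", ns)
  mods <- xml2::xml_attr(
    xml2::xml_find_all(r24, ".//s:modifierSpeciesReference", ns),
    "species")
  expect_setequal(mods, c("Bcat_TCF", "Bcat"))
  # every parameter referenced by a kinetic law is declared
  mml <- c(m = "http://www.w3.org/1998/Math/MathML")
  cis <- unique(trimws(xml2::xml_text(
    xml2::xml_find_all(doc, ".//m:ci", mml))))
  declared <- c(speciesNames(), parameterNames())
  expect_true(all(cis %in% declared))
})
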