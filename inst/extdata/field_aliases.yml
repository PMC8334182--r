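# Field-alias dictionary: canonical field name -> header spellings seen in
# source documents. '.?' is a single optional character; '\W' edges are
# compiled boundary-safe. Matching is case-insensitive.
Drug:
  - '\WActive.?ingredient.?\W'
  - '\WResidues.?detected\W'
  - '\WDetected.?residues\W'
  - '\WAntimicrobial.?drug\W'
  - '\WAntimicrobial.?\W'
  - '\WAntimicrobial.?agent.?\W'
  - '\WBeta.?lactam drug.?\W'
  - '\WBeta lactams\W'
  - '\WTetracycline.?\W'
  - '\WQuinolone.?drug.?\W'
  - '\WDrug\W'
Sensitivity:
  - '\WConcentration for positive ppb\W'
  - '\WCharm.?sl\W'
  - '\WTest.?Sensitivity\W'
  - '\WConcentration\W'
  - '\WPositive Concentration\W'
  - '\WDetection level\W'
  - '\WDetection range\W'
  - '\WDetection range ppb\W'
  - '\WSensitivity\W'
Test:
  - '\WTest\W'
  - '\WTest Name\W'
Matrix:
  - '\WMatrix\W'
  - '\WSpecimen\W'
MRL:
  - '\WCODEX\W'
  - '\WTechnical Regulation\W'
  - '\WMRPL\W'
  - '\WFederation\W'
  - '\WRegulation\W'
  - '\WImport Regulation\W'
  - '\WMRL.?ppb\W'
Tolerance:
  - '\WAction Level\W'
  - '\WSafe level\W'
  - '\WSafety level\W'
Type:
  - '\WTest.?type\W'
  - '\WAssay.?type\W'
  - '\WMethod\W'
  - '\WFormat\W'
Animal:
  - '\WAnimal\W'
  - '\WSpecies\W'
  - '\WCommodity\W'
Manufacturer:
  - '\WManufacturer\W'
  - '\WCompany\W'
  - '\WSupplier\W'
Unit:
  - '\WUnit.?\W'
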