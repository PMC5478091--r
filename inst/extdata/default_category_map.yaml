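# Default disease-category map for main cause-of-death classification.
# Keys may be chapter ids (Roman numerals), block ids ("start-end"), or
# three-character categories; resolution order is category > block > chapter,
# with unmatched codes falling back to `default`.
# Categories: infectious_diseases, malignant_tumors, congenital_malformations,
# other_diseases, nonconclusive.
chapters:
  I: infectious_diseases
  XVII: congenital_malformations
blocks:
  # chapter II malignant blocks (C00-C97); benign/in-situ D00-D48 fall to default
  C00-C14: malignant_tumors
  C15-C26: malignant_tumors
  C30-C39: malignant_tumors
  C40-C41: malignant_tumors
  C43-C44: malignant_tumors
  C45-C49: malignant_tumors
  C50-C50: malignant_tumors
  C51-C58: malignant_tumors
  C60-C63: malignant_tumors
  C64-C68: malignant_tumors
  C69-C72: malignant_tumors
  C73-C75: malignant_tumors
  C76-C80: malignant_tumors
  C81-C96: malignant_tumors
  C97-C97: malignant_tumors
  # infection blocks living outside chapter I: pneumonia and acute lower
  # respiratory infection, CNS infection, peritonitis, pyelonephritis
  J09-J18: infectious_diseases
  J20-J22: infectious_diseases
  G00-G09: infectious_diseases
  K65-K67: infectious_diseases
  N10-N16: infectious_diseases
  # ill-defined and unknown causes of mortality
  R95-R99: nonconclusive
categories: {}
default: other_diseases
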