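[
  {
    "group_id": "corolla_size",
    "label": "Corolla size",
    "kind": "categorical",
    "states": ["minute", "small", "medium", "large"]
  },
  {
    "group_id": "corolla_shape",
    "label": "Corolla shape",
    "kind": "categorical",
    "states": ["tube", "cup", "urn", "globose", "bell", "oblong"]
  },
  {
    "group_id": "corolla_colour",
    "label": "Corolla colour",
    "kind": "categorical",
    "states": ["white", "cream", "yellow", "orange", "red", "pink", "purple", "green", "brown"]
  },
  {
    "group_id": "stem_hairiness",
    "label": "Hairiness of stem",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "leaf_hairiness",
    "label": "Hairiness of leaf",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "pedicel_hairiness",
    "label": "Hairiness of pedicel",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "sepal_hairiness",
    "label": "Hairiness of sepal",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "corolla_hairiness",
    "label": "Hairiness of corolla",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "ovary_hairiness",
    "label": "Hairiness of ovary",
    "kind": "categorical",
    "states": ["glabrous", "hairy", "glandular"]
  },
  {
    "group_id": "style_exserted",
    "label": "Style exserted",
    "kind": "binary",
    "states": ["yes", "no"]
  },
  {
    "group_id": "anthers_exserted",
    "label": "Anthers exserted",
    "kind": "binary",
    "states": ["yes", "no"]
  },
  {
    "group_id": "anther_appendages",
    "label": "Anther appendages",
    "kind": "binary",
    "states": ["present", "absent"]
  },
  {
    "group_id": "stamen_number",
    "label": "Number of stamens",
    "kind": "count",
    "states": ["4", "5", "6", "7", "8"]
  },
  {
    "group_id": "sepal_number",
    "label": "Number of sepals",
    "kind": "count",
    "states": ["3", "4"]
  },
  {
    "group_id": "corolla_lobe_number",
    "label": "Number of corolla lobes",
    "kind": "count",
    "states": ["3", "4", "5"]
  },
  {
    "group_id": "leaves_per_whorl",
    "label": "Leaves per whorl",
    "kind": "count",
    "states": ["3", "4", "5", "6"]
  },
  {
    "group_id": "bract_number",
    "label": "Number of bracts",
    "kind": "count",
    "states": ["1", "2", "3"]
  },
  {
    "group_id": "sepal_corolla_ratio",
    "label": "Sepal:corolla length ratio",
    "kind": "categorical",
    "states": ["under-half", "about-half", "over-half", "equalling-or-longer"]
  },
  {
    "group_id": "resprouting",
    "label": "Resprouting after fire",
    "kind": "binary",
    "states": ["yes", "no"]
  },
  {
    "group_id": "flowering_month",
    "label": "Flowering month",
    "kind": "month",
    "states": ["Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct", "Nov", "Dec"]
  },
  {
    "group_id": "region",
    "label": "Region",
    "kind": "region",
    "states": ["Cape Peninsula", "SW Cape", "S Cape", "Agulhas Plain", "Langeberg", "NW Cape", "Karoo Mountains", "E Cape", "KZ-Natal", "North South Africa", "Tropical Africa", "Madagascar", "Europe"]
  }
]
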