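{
  "description": "Default content-unit lexicon for the Cookie Theft picture-description stimulus. Package default, editable: the study-specific unit list is not public, so this file enumerates the scene's standard objects, actors and actions. Each entry maps one unit to its lowercase surface forms, whether it is related to the depicted scenario, and the side of the picture it occupies (left, right, or both for non-localized units).",
  "entries": [
    {"unit_id": "boy", "surface_forms": ["boy", "brother", "son"], "relatedness": "related", "location": "left"},
    {"unit_id": "girl", "surface_forms": ["girl", "sister", "daughter"], "relatedness": "related", "location": "left"},
    {"unit_id": "stool", "surface_forms": ["stool", "ladder"], "relatedness": "related", "location": "left"},
    {"unit_id": "cookie_jar", "surface_forms": ["cookie jar", "jar"], "relatedness": "related", "location": "left"},
    {"unit_id": "cookie", "surface_forms": ["cookie", "cookies"], "relatedness": "related", "location": "left"},
    {"unit_id": "cabinet", "surface_forms": ["cabinet", "cupboard", "shelf"], "relatedness": "related", "location": "left"},
    {"unit_id": "dog", "surface_forms": ["dog", "puppy"], "relatedness": "related", "location": "left"},
    {"unit_id": "falling", "surface_forms": ["falling", "tipping", "wobbling"], "relatedness": "related", "location": "left"},
    {"unit_id": "reaching", "surface_forms": ["reaching", "grabbing", "taking"], "relatedness": "related", "location": "left"},
    {"unit_id": "mother", "surface_forms": ["mother", "woman", "mom", "lady"], "relatedness": "related", "location": "right"},
    {"unit_id": "sink", "surface_forms": ["sink", "basin"], "relatedness": "related", "location": "right"},
    {"unit_id": "water", "surface_forms": ["water"], "relatedness": "related", "location": "right"},
    {"unit_id": "overflowing", "surface_forms": ["overflowing", "overflow", "spilling"], "relatedness": "related", "location": "right"},
    {"unit_id": "dishes", "surface_forms": ["dishes", "dish", "plate", "plates"], "relatedness": "related", "location": "right"},
    {"unit_id": "washing", "surface_forms": ["washing", "drying", "wiping"], "relatedness": "related", "location": "right"},
    {"unit_id": "window", "surface_forms": ["window"], "relatedness": "related", "location": "right"},
    {"unit_id": "curtains", "surface_forms": ["curtains", "curtain"], "relatedness": "related", "location": "right"},
    {"unit_id": "counter", "surface_forms": ["counter", "countertop"], "relatedness": "related", "location": "right"},
    {"unit_id": "kitchen", "surface_forms": ["kitchen"], "relatedness": "related", "location": "both"},
    {"unit_id": "family", "surface_forms": ["family"], "relatedness": "related", "location": "both"},
    {"unit_id": "garden", "surface_forms": ["garden", "yard"], "relatedness": "unrelated", "location": "both"},
    {"unit_id": "car", "surface_forms": ["car", "truck"], "relatedness": "unrelated", "location": "both"},
    {"unit_id": "weather", "surface_forms": ["weather", "rain"], "relatedness": "unrelated", "location": "both"},
    {"unit_id": "television", "surface_forms": ["television", "tv"], "relatedness": "unrelated", "location": "both"}
  ]
}
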