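{
  "language": "fr",
  "ius": [
    {"name": "boy", "keywords": ["garçon", "garcon", "frère", "frere", "fils"],
     "half": "left", "quadrant": "SW", "stripe": "most-left"},
    {"name": "girl", "keywords": ["fille", "sœur", "soeur"],
     "half": "left", "quadrant": "SW", "stripe": "center-left"},
    {"name": "woman", "keywords": ["femme", "mère", "mere", "maman", "dame"],
     "half": "right", "quadrant": "SE", "stripe": "center-right"},
    {"name": "kitchen", "keywords": ["cuisine"],
     "half": "right", "quadrant": "NE", "stripe": "center-right"},
    {"name": "exterior", "keywords": ["extérieur", "exterieur", "jardin", "dehors", "allée"],
     "half": "right", "quadrant": "NE", "stripe": "most-right"},
    {"name": "cookie", "keywords": ["biscuit", "gâteau", "gateau", "cookie"],
     "half": "left", "quadrant": "NW", "stripe": "center-left"},
    {"name": "jar", "keywords": ["bocal", "pot", "boîte", "boite", "jarre"],
     "half": "left", "quadrant": "NW", "stripe": "center-left"},
    {"name": "stool", "keywords": ["tabouret", "escabeau"],
     "half": "left", "quadrant": "SW", "stripe": "most-left"},
    {"name": "sink", "keywords": ["évier", "evier", "lavabo"],
     "half": "right", "quadrant": "SE", "stripe": "center-right"},
    {"name": "plate", "keywords": ["assiette"],
     "half": "right", "quadrant": "SE", "stripe": "most-right"},
    {"name": "dishcloth", "keywords": ["torchon", "chiffon", "essuie-tout"],
     "half": "right", "quadrant": "SE", "stripe": "center-right"},
    {"name": "water", "keywords": ["eau"],
     "half": "right", "quadrant": "SE", "stripe": "most-right"},
    {"name": "window", "keywords": ["fenêtre", "fenetre"],
     "half": "right", "quadrant": "NE", "stripe": "most-right"},
    {"name": "cupboard", "keywords": ["placard", "armoire", "étagère", "etagere"],
     "half": "left", "quadrant": "NW", "stripe": "center-left"},
    {"name": "dish", "keywords": ["vaisselle", "plat", "tasse"],
     "half": "right", "quadrant": "SE", "stripe": "center-right"},
    {"name": "curtain", "keywords": ["rideau"],
     "half": "right", "quadrant": "NE", "stripe": "most-right"}
  ]
}
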