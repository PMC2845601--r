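{
  "comment": "Controlled vocabulary of M2 visual-phenotype classes and subclasses for the Red Setter tomato mutant collection, with the number of plants recorded per subclass. 17 classes, 51 subclasses.",
  "classes": [
    {"class": "Seed", "subclasses": [
      {"subclass": "No germination", "plants": 3904},
      {"subclass": "Seedling lethality", "plants": 1674}]},
    {"class": "Cotyledons", "subclasses": [
      {"subclass": "Colour", "plants": 264},
      {"subclass": "Number", "plants": 82},
      {"subclass": "Morphology", "plants": 17},
      {"subclass": "Size", "plants": 2},
      {"subclass": "Other cotyledon development", "plants": 3}]},
    {"class": "Plant size", "subclasses": [
      {"subclass": "Small plant", "plants": 303},
      {"subclass": "Large plant", "plants": 4}]},
    {"class": "Plant habit", "subclasses": [
      {"subclass": "Aborted growth", "plants": 81},
      {"subclass": "Branching", "plants": 109},
      {"subclass": "Internode length", "plants": 16},
      {"subclass": "Other plant habit", "plants": 174}]},
    {"class": "Leaf morphology", "subclasses": [
      {"subclass": "Leaf complexity", "plants": 27},
      {"subclass": "Leaf size", "plants": 98},
      {"subclass": "Leaf texture", "plants": 16},
      {"subclass": "Leaf width", "plants": 12},
      {"subclass": "Other leaf development", "plants": 188}]},
    {"class": "Leaf colour", "subclasses": [
      {"subclass": "Dark green leaf", "plants": 19},
      {"subclass": "Dull green/grey leaf", "plants": 19},
      {"subclass": "Purple leaf", "plants": 17},
      {"subclass": "Variegation", "plants": 20},
      {"subclass": "White leaf", "plants": 4},
      {"subclass": "Yellow leaf", "plants": 28},
      {"subclass": "Yellow-green leaf", "plants": 79}]},
    {"class": "Flowering", "subclasses": [
      {"subclass": "Late flowering", "plants": 142}]},
    {"class": "Inflorescence", "subclasses": [
      {"subclass": "Inflorescence structure", "plants": 28}]},
    {"class": "Flower morphology", "subclasses": [
      {"subclass": "Flower homeotic mutation", "plants": 5},
      {"subclass": "Flower organ size", "plants": 10},
      {"subclass": "Flower organ width", "plants": 12},
      {"subclass": "Other flower morphology", "plants": 4}]},
    {"class": "Flower colour", "subclasses": [
      {"subclass": "Pale yellow flower", "plants": 13},
      {"subclass": "White flower", "plants": 5}]},
    {"class": "Fruit size", "subclasses": [
      {"subclass": "Large fruit", "plants": 212},
      {"subclass": "Small fruit", "plants": 192}]},
    {"class": "Fruit morphology", "subclasses": [
      {"subclass": "Long fruit", "plants": 43},
      {"subclass": "Other fruit morphology", "plants": 2},
      {"subclass": "Rounded fruit", "plants": 4}]},
    {"class": "Fruit colour", "subclasses": [
      {"subclass": "Dark red fruit", "plants": 0},
      {"subclass": "Green fruit", "plants": 0},
      {"subclass": "Orange fruit", "plants": 0},
      {"subclass": "Yellow fruit", "plants": 3}]},
    {"class": "Fruit number", "subclasses": [
      {"subclass": "Absent", "plants": 1073},
      {"subclass": "Few", "plants": 1393},
      {"subclass": "Many", "plants": 64}]},
    {"class": "Sterility", "subclasses": [
      {"subclass": "Partial sterility", "plants": 2125},
      {"subclass": "Total sterility", "plants": 576}]},
    {"class": "Seed germination into fruit", "subclasses": [
      {"subclass": "Seed germination into fruit", "plants": 208}]},
    {"class": "Disease and stress response", "subclasses": [
      {"subclass": "Necrosis", "plants": 48},
      {"subclass": "Wilting", "plants": 80},
      {"subclass": "Other disease response", "plants": 0}]}
  ]
}
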