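From the passage, extract the attributes of the dish entity it describes:
name, ingredient composition, cooking method and dietary benefits. Leave
fields you cannot support from the passage empty; never invent values.

Passage: {passage}

Return only a JSON object with keys "name", "ingredients", "cooking_method",
"dietary_benefits".
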