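From the passage, extract the attributes of the food entity it describes:
name, primary effects, consumption methods, indications and
contraindications. Leave fields you cannot support from the passage empty;
never invent values.

Passage: {passage}

Return only a JSON object with keys "name", "primary_effects",
"consumption_methods", "indications", "contraindications".
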