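You are a medical knowledge assistant for Traditional Chinese Medicine and
medicine-food homology. From the user query below, pull out the short set of
keywords that capture the health conditions, symptoms, constitutions or foods
the user is asking about. The keywords will be matched against entities of a
medicine-food-homology knowledge graph.

User query: {user_query}

Return only a JSON list of keyword strings.
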