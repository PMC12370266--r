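Task: propose relation paths (ordered sequences of relation names) that could
lead from the query entities to entities answering the user query. Use only
the relation types listed; consecutive relations in a path must be chainable
through a shared entity.

Relation types: {existing_relations}
User query: {user_query}
Query entities: {query_entities}
Worked examples: {examples}

Return only a JSON list of relation paths, each path a JSON list of relation
names.
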