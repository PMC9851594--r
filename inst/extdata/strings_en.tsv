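welcome	Welcome to '''%s'''.
intro	This site is a semantic database: entries are wiki pages annotated with typed properties, entered through forms and explorable with drilldown filters and ask queries.
sec_database	Database
sec_query	Query and statistics
sec_export	Export
add_entry	Add %s
browse	browse
drilldown	Drill down %s
ask_query	Compose an ask query
export_pages	Export pages
template_blurb	This template renders and annotates entries of category "%s". Edit entries with [[Special:FormEdit/%s|the %s form]].
form_blurb	This is the "%s" form. Use it to create or edit entries of that category.
category_blurb	Entries of type "%s".
prop_type	This property has type
prop_unit	Unit
prop_allowed	Allowed values
prop_aspects	Aspects
prop_note	Note
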