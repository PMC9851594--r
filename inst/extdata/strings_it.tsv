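welcome	Benvenuti in '''%s'''.
intro	Questo sito è una base di dati semantica: le voci sono pagine wiki annotate con proprietà tipizzate, inserite tramite moduli ed esplorabili con filtri drilldown e interrogazioni ask.
sec_database	Base di dati
sec_query	Interrogazioni e statistiche
sec_export	Esportazione
add_entry	Aggiungi %s
browse	sfoglia
drilldown	Drilldown %s
ask_query	Componi una interrogazione ask
export_pages	Esporta pagine
template_blurb	Questo template visualizza e annota le voci della categoria "%s". Modifica le voci con [[Special:FormEdit/%s|il modulo %s]].
form_blurb	Questo è il modulo "%s". Usalo per creare o modificare le voci di quella categoria.
category_blurb	Voci di tipo "%s".
prop_type	Questa proprietà ha tipo
prop_unit	Unità
prop_allowed	Valori ammessi
prop_aspects	Aspetti
prop_note	Nota
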