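analyte,failed_scope
Aripiprazole,within_run
Diphenhydramine,within_run
Ketamine,within_run
Melperone,within_run
Pethidine,within_run
Sertraline,within_run
Tilidine,within_run
Tilidine-M (nor-),within_run
Olanzapine,between_run
Pethidine-M (nor-),between_run
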