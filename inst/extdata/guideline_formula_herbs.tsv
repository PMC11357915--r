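formula_id	herb_id
F1	Codonopsis Radix
F1	Atractylodis Macrocephalae Rhizoma
F1	Poria
F1	Persicae Semen
F1	Bupleuri Radix
F1	Angelicae Sinensis Radix
F1	Paeoniae Radix Alba
F1	Akebiae Caulis
F1	Magnoliae Officinalis Cortex
F1	Gardeniae Fructus
F1	Curcumae Rhizoma
F1	Glycyrrhizae Radix et Rhizoma
F2	Artemisiae Scopariae Herba
F2	Gardeniae Fructus
F2	Rhei Radix et Rhizoma
F2	Lysimachiae Herba
F2	Polyporus
F2	Bupleuri Radix
F2	Paeoniae Radix Alba
F2	Curcumae Radix
F2	Toosendan Fructus
F2	Aurantii Fructus
F2	Scutellariae Barbatae Herba
F2	Paridis Rhizoma
F2	Plantaginis Herba
F2	Alismatis Rhizoma
F3	Gentianae Radix et Rhizoma
F3	Scutellariae Barbatae Herba
F3	Gardeniae Fructus
F3	Alismatis Rhizoma
F3	Akebiae Caulis
F3	Plantaginis Semen
F3	Rehmanniae Radix
F3	Bupleuri Radix
F3	Persicae Semen
F3	Curcumae Rhizoma
F3	Rhei Radix et Rhizoma
F3	Rubiae Radix et Rhizoma
F3	Moutan Cortex
F3	Glycyrrhizae Radix et Rhizoma
F4	Astragali Radix
F4	Codonopsis Radix
F4	Atractylodis Macrocephalae Rhizoma
F4	Poriae Cutis
F4	Cyperi Rhizoma
F4	Aurantii Fructus
F4	Citri Reticulatae Pericarpium
F4	Arecae Pericarpium
F4	Benincasae Exocarpium
F4	Alismatis Rhizoma
F4	Coicis Semen
F4	Solani Nigri Herba
F4	Persicae Semen
F4	Curcumae Rhizoma
F4	Scutellariae Barbatae Herba
F4	Glycyrrhizae Radix et Rhizoma
F5	Rehmanniae Radix
F5	Glehniae Radix
F5	Ophiopogonis Radix
F5	Angelicae Sinensis Radix
F5	Lycii Fructus
F5	Mori Fructus
F5	Toosendan Fructus
F5	Paeoniae Radix Rubra
F5	Trionycis Carapax
F5	Ligustri Lucidi Fructus
F5	Ecliptae Herba
F5	Moutan Cortex
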