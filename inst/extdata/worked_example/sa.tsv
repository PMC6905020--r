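synth001	   0.853631    0.730163    0.452258    0.210205    0.436583    0.045781    0.754569     0.72967    0.828931    0.831604    0.248837    0.278793    0.157325    0.926996    0.307989    0.937334    0.075165    0.726446    0.892495    0.750334    0.289473    0.191908    0.299214    0.078781    0.715639    0.630834    0.331566    0.373666    0.274356    0.032214    0.316308    0.529279    0.826675    0.759491    0.141367    0.823039    0.149108    0.217542    0.828295     0.82135    0.599309    0.352316    0.757383    0.941553    0.796884    0.826403    0.079689     0.87028    0.835717    0.165919    0.100068     0.33704    0.219446    0.356956    0.393892    0.147442
synth002	   0.739088     0.37077    0.363307    0.164708    0.872456    0.526194    0.707985    0.617028    0.164809    0.782459     0.76155    0.195218    0.452688    0.632428    0.300347    0.587307    0.912404    0.530374    0.285755    0.210699     0.19703    0.642785    0.758711    0.920017    0.102463    0.363193    0.018363    0.346697    0.209906    0.267562    0.579455    0.795911    0.331048    0.844874    0.804079     0.31716    0.908207    0.200216    0.030902    0.155981    0.636255     0.09902
synth003	   0.312594    0.123955    0.559814    0.351122     0.46088    0.263046    0.436961    0.878905    0.052983    0.355976    0.143047    0.882486    0.046407    0.666925    0.961558     0.04921    0.860166     0.90762    0.265719    0.048996     0.04031    0.262209    0.252274    0.731452    0.968195    0.627279    0.550616    0.322528    0.202939    0.521006    0.847316    0.834878     0.08392    0.431473    0.804471    0.185181    0.428971    0.728993    0.680935    0.387355    0.815561
synth004	   0.950916    0.681174    0.287121    0.120059    0.226364    0.331706    0.379132    0.897619    0.653688    0.599502    0.357914    0.159113    0.215375    0.012481    0.846437    0.080367    0.762693    0.453607    0.340964     0.73747    0.773272    0.451892     0.54724    0.358165    0.658068    0.409858    0.157615    0.476166    0.337068    0.341889    0.536695    0.236437    0.387891    0.209058    0.482656     0.55492    0.390339    0.209806    0.089634    0.341832    0.704461    0.696125    0.468209    0.102254    0.177468    0.344279    0.247752    0.860134    0.115508    0.267264    0.685717    0.860425    0.334308    0.100118     0.52301    0.273306    0.822231     0.58732    0.658272
synth005	   0.715191    0.284263    0.163462    0.111695    0.771227     0.44309    0.829171    0.795799    0.156129    0.487363    0.596992    0.146842    0.939067    0.811777    0.683842    0.608992    0.807735    0.147275    0.726376     0.09726    0.537261    0.820169    0.535453    0.944994    0.105675    0.328891    0.853821    0.310303    0.658645    0.641305    0.087476    0.701322    0.586478     0.37553    0.591911    0.401166    0.071557    0.579358    0.326974    0.452365
synth006	   0.442006    0.455409    0.454937    0.144988    0.186325    0.171256    0.163203    0.928876    0.750299    0.624032    0.043255    0.454122    0.970725    0.606136    0.324619     0.70856    0.040731    0.119855    0.125086    0.714218    0.918698    0.219354    0.140586    0.245751    0.664362    0.708548    0.408588    0.215043    0.086395    0.412259    0.955582    0.511841    0.967505    0.095743    0.736155    0.659359    0.415793    0.684681     0.65146    0.958989    0.475086    0.169798    0.297198    0.414127    0.083206    0.603131    0.266239    0.632614    0.338429    0.181659    0.775033    0.863764    0.879508    0.767536    0.218193    0.656636    0.876829    0.790421
synth007	   0.440089    0.952294    0.162707    0.299764    0.893568    0.529287    0.800442     0.94289    0.367478    0.156077    0.089062    0.702642    0.224344    0.180396    0.089424    0.911504    0.463081    0.456879    0.135768    0.100121    0.070414    0.808549    0.583893    0.850405    0.522418    0.777726    0.916314    0.380021    0.161657    0.168868    0.918182      0.2092    0.285148    0.524967    0.493246    0.467814    0.679974    0.014851    0.353487    0.399521    0.159663    0.465622    0.568312    0.252835    0.496092    0.748941    0.238034    0.367777    0.741373     0.90526    0.376066
synth008	   0.406695    0.266098    0.226649     0.05005    0.159314    0.644959    0.170942    0.931591    0.327404     0.22564    0.773868     0.75299    0.196054    0.670409    0.758169    0.432499     0.10893    0.541764    0.808045    0.545335    0.805119     0.14489    0.638983    0.891701    0.685544     0.86584    0.127618    0.609693    0.264932    0.868862     0.21987    0.900377    0.351318    0.164599    0.349237    0.659684     0.20221    0.242113    0.780334    0.125038    0.369999    0.262298    0.928273    0.951445     0.74459    0.563182    0.782453    0.114551    0.228263    0.578225     0.84063    0.891204     0.08387    0.062136    0.598112    0.640474     0.75374    0.243183    0.335254    0.930438
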